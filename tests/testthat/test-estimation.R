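# Parameter-estimation formulas: rate conversions, pooled rates, relative
# risks, moment back-calculation, calibration, mortality schedules.

test_that("cumulative risk converts to a weekly incidence rate and back", {
  expect_equal(incidence_rate_from_cumulative(0, 10), 0)
  # hand evaluations of -ln(1 - CR) / T
  expect_equal(incidence_rate_from_cumulative(0.0175, 8), -log(0.9825) / 8)
  expect_equal(incidence_rate_from_cumulative(0.122, 8), -log(0.878) / 8)
  expect_error(incidence_rate_from_cumulative(1, 8), "\\[0, 1\\)")
  expect_error(incidence_rate_from_cumulative(0.5, 0), "positive")

  # round trip CR -> IR -> CR' recovers CR to machine precision
  set.seed(11)
  cr <- runif(50, 0, 0.99)
  tt <- runif(50, 0.5, 60)
  ir <- incidence_rate_from_cumulative(cr, tt)
  expect_equal(1 - exp(-ir * tt), cr, tolerance = 1e-12)
})

test_that("pooled incidence rate is the patient-weighted mean of study rates", {
  one <- data.frame(cumulative_risk = 0.02, followup_weeks = 10, n_patients = 100)
  expect_equal(pooled_incidence_rate(one), -log(0.98) / 10)
  two_same <- rbind(one, one)
  expect_equal(pooled_incidence_rate(two_same), -log(0.98) / 10)

  mixed <- data.frame(cumulative_risk = c(0.02, 0.01),
                      followup_weeks = c(10, 5),
                      n_patients = c(100, 50))
  oracle <- (100 * (-log(0.98) / 10) + 50 * (-log(0.99) / 5)) / 150
  expect_equal(pooled_incidence_rate(mixed), oracle)

  expect_error(pooled_incidence_rate(mixed[0, ]), "non-empty")
  expect_error(pooled_incidence_rate(data.frame(x = 1)), "missing column")
})

test_that("study CSV reader derives cumulative risks from counts", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("label,events,n,followup_weeks",
               "studyA,10,82,8", "studyB,1,57,8"), path)
  st <- read_studies(path)
  expect_equal(st$cumulative_risk, c(10 / 82, 1 / 57))
  expect_equal(st$n_patients, c(82, 57))
  writeLines(c("label,events,n,followup_weeks", "bad,9,8,8"), path)
  expect_error(read_studies(path), "events")
})

test_that("relative risk reproduces the published dysphagia-pneumonia estimates", {
  # aspirating dysphagia (24/83) vs no dysphagia (5/143): 8.27 (3.28; 20.85)
  rr1 <- relative_risk(24, 83, 5, 143)
  expect_equal(round(rr1$point, 2), 8.27)
  expect_equal(round(rr1$ci_low, 2), 3.28)
  expect_equal(round(rr1$ci_high, 2), 20.85)
  # non-aspirating dysphagia (15/155) vs no dysphagia: 2.77 (1.03; 7.42)
  rr2 <- relative_risk(15, 155, 5, 143)
  expect_equal(round(rr2$point, 2), 2.77)
  expect_equal(round(rr2$ci_low, 2), 1.03)
  expect_equal(round(rr2$ci_high, 2), 7.42)
})

test_that("relative risk has sound estimator properties", {
  rr <- relative_risk(5, 100, 5, 100)
  expect_equal(rr$point, 1)
  expect_lt(rr$ci_low, 1)
  expect_gt(rr$ci_high, 1)

  set.seed(21)
  for (i in 1:20) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    a <- sample.int(n1 - 1, 1); b <- sample.int(n2 - 1, 1)
    est <- relative_risk(a, n1, b, n2)
    expect_equal(est$point, (a / n1) / (b / n2))  # brute-force ratio
    expect_lte(est$ci_low, est$point)
    expect_gte(est$ci_high, est$point)
    swapped <- relative_risk(b, n2, a, n1)
    expect_equal(swapped$point, 1 / est$point)
  }

  expect_error(relative_risk(5, 100, 0, 100), "undefined")
  zero <- relative_risk(0, 100, 5, 100)
  expect_equal(zero$point, 0)
  expect_false(zero$reliable)
})

test_that("rates scaled by relative risks convert to cycle probabilities", {
  expect_equal(weekly_probability(0), 0)
  expect_equal(weekly_probability(0.004036, 8.27), 1 - exp(-0.004036 * 8.27))
  expect_equal(weekly_probability(0.004036, 1), 1 - exp(-0.004036))
  # small-argument behaviour: p ~ ir * rr
  expect_equal(weekly_probability(1e-6, 2), 2e-6, tolerance = 1e-5)
  expect_error(weekly_probability(-0.1), "non-negative")
  expect_error(weekly_probability(0.1, 0), "positive")
})

test_that("standard deviations back-calculate from symmetric intervals", {
  z <- qnorm(0.975)
  expect_equal(sd_from_interval(0.32, 0.42), 0.10 / (2 * z))
  expect_equal(sd_from_interval(0.135, 0.165), 0.03 / (2 * z))
  expect_equal(sd_from_interval(0.4, 0.4), 0)
  expect_error(sd_from_interval(0.5, 0.4), "low")
})

test_that("beta method of moments recovers the target mean and SD", {
  expect_equal(beta_from_moments(0.5, sqrt(1 / 12)),
               c(shape1 = 1, shape2 = 1), tolerance = 1e-12)
  cases <- list(c(0.37, 0.025511), c(0.15, 0.0076532), c(0.13, 0.012755))
  for (cs in cases) {
    sh <- beta_from_moments(cs[1], cs[2])
    m <- sh[1] / sum(sh)
    v <- sh[1] * sh[2] / (sum(sh)^2 * (sum(sh) + 1))
    expect_equal(unname(m), cs[1], tolerance = 1e-10)
    expect_equal(unname(sqrt(v)), cs[2], tolerance = 1e-10)
  }
  expect_error(beta_from_moments(0.5, 0.6), "variance")

  # large-sample check: draws reproduce the mean within 3 standard errors
  sh <- beta_from_moments(0.37, 0.025511)
  set.seed(31)
  x <- rbeta(1e6, sh[1], sh[2])
  expect_lt(abs(mean(x) - 0.37), 3 * 0.025511 / sqrt(1e6))
})

test_that("gamma and lognormal back-calculations recover their inputs", {
  g <- gamma_from_moments(1924, 0.2 * 1924)
  expect_equal(unname(g[1] / g[2]), 1924)
  expect_equal(unname(sqrt(g[1]) / g[2]), 0.2 * 1924)
  ln <- lognormal_from_ci(2.99, 2.44, 3.66)
  expect_equal(unname(exp(ln[1])), 2.99)
  expect_equal(unname(ln[2]), (log(3.66) - log(2.44)) / (2 * qnorm(0.975)))
})

test_that("resolution calibration matches one-step ratios on anchors", {
  # flat prevalence held at 1 through day 365: nothing ever resolves
  flat <- data.frame(time_days = c(0, 365), fraction_with_dysphagia = c(1, 1))
  expect_equal(as.numeric(calibrate_resolution(flat)), rep(0, 52))

  # one-step anchor ratio: halving by day 7 means week-1 probability 0.5
  half <- data.frame(time_days = c(0, 7), fraction_with_dysphagia = c(1, 0.5))
  expect_equal(as.numeric(calibrate_resolution(half))[1], 0.5)

  # anchors generated by constant 5% weekly resolution are recovered
  w <- 0:52
  geo <- data.frame(time_days = 7 * w, fraction_with_dysphagia = 0.95^w)
  sched <- calibrate_resolution(geo)
  expect_equal(as.numeric(sched), rep(0.05, 52), tolerance = 1e-10)

  # prevalence reaches ~0 by the final week under the one-year assumption
  base <- data.frame(time_days = c(0, 7, 28, 180),
                     fraction_with_dysphagia = c(1, 0.5, 0.25, 0.08))
  s <- calibrate_resolution(base)
  expect_lt(prod(1 - s), 1e-3)

  bad <- data.frame(time_days = c(0, 7, 28),
                    fraction_with_dysphagia = c(1, 0.4, 0.6))
  expect_error(calibrate_resolution(bad), "non-increasing")
  expect_error(calibrate_resolution(
    data.frame(time_days = c(0, 7), fraction_with_dysphagia = c(1, 1.2))),
    "\\[0, 1\\]")
  expect_error(calibrate_resolution(
    data.frame(time_days = c(0, 7), fraction_with_dysphagia = c(0.8, 0.5))),
    "day 0")
})

test_that("calibration and prevalence simulation are inverse on anchor points", {
  set.seed(41)
  for (i in 1:15) {
    sched <- runif(52, 0, 0.25)
    anchor_days <- sort(c(0, 7 * sample(1:52, 5)))
    pts <- simulate_prevalence(sched, anchor_days)
    recovered <- calibrate_resolution(pts)
    back <- simulate_prevalence(recovered, anchor_days)
    expect_equal(back$fraction_with_dysphagia, pts$fraction_with_dysphagia,
                 tolerance = 1e-10)
  }
})

test_that("mortality schedule is piecewise constant with three levels", {
  s <- mortality_schedule(0.046, 0.0096, 0.0024, 52)
  expect_length(s, 52)
  expect_equal(unique(s), c(0.046, 0.0096, 0.0024))
  expect_equal(s[1:4], rep(0.046, 4))
  expect_equal(s[5:13], rep(0.0096, 9))
  expect_equal(s[14:52], rep(0.0024, 39))
  expect_lte(length(unique(s)), 3)

  expect_equal(mortality_schedule(0, 0, 0, 52), rep(0, 52))
  expect_warning(short <- mortality_schedule(horizon_weeks = 10), "truncated")
  expect_length(short, 10)

  # 52-week survival equals the closed-form product of weekly survival
  expect_equal(prod(1 - s), (1 - 0.046)^4 * (1 - 0.0096)^9 * (1 - 0.0024)^39)
})

test_that("logarithmic mortality interpolation fits and converts to weekly risks", {
  t <- c(30, 90, 180, 360)
  exact <- fit_log_survival(t, 0.1 * log(t) + 0.02)
  expect_equal(exact$a, 0.1, tolerance = 1e-10)
  expect_equal(exact$b, 0.02, tolerance = 1e-10)
  expect_equal(exact$r_squared, 1, tolerance = 1e-10)

  two <- fit_log_survival(c(30, 90), c(0.1, 0.2))
  expect_equal(two$r_squared, 1, tolerance = 1e-10)

  expect_error(fit_log_survival(30, 0.1), "two time points")
  expect_error(fit_log_survival(c(0, 30), c(0, 0.1)), "positive")

  sched <- log_fit_mortality_schedule(exact, 52)
  expect_length(sched, 52)
  expect_true(all(sched >= 0 & sched <= 1))
  # conditional weekly risks telescope back to the fitted cumulative curve
  m <- function(tt) 0.1 * log(pmax(tt, 1)) + 0.02
  surv <- cumprod(1 - sched)
  expect_equal(surv[52], (1 - m(364)) / (1 - m(0)), tolerance = 1e-10)
})
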