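# Markov cohort engine: transition structure, occupancy conservation,
# closed-form special cases, and convergence to the static model under a
# degenerate configuration (the two-model cross-validation).

base_dynamic <- function() base_case_fixture()$dynamic

test_that("transition rows are probability vectors with the stated structure", {
  p <- base_dynamic()
  states <- markov_states()
  for (w in c(1, 5, 20, 52)) {
    for (s in states) {
      row <- build_transition_row(s, w, "comparator", p)
      expect_equal(sum(row), 1, tolerance = 1e-12)
      expect_true(all(row >= 0 & row <= 1))
    }
  }
  # death is absorbing
  dead <- build_transition_row("DEAD", 10, params = p)
  expect_equal(unname(dead["DEAD"]), 1)
  # tunnel chain: week 1 -> week 2 -> originating dysphagia state (or death)
  ap1 <- build_transition_row("AP1_ASP", 10, params = p)
  expect_equal(sum(ap1[c("AP2_ASP", "DEAD")]), 1)
  ap2 <- build_transition_row("AP2_NO_ASP", 10, params = p)
  expect_equal(sum(ap2[c("DYS_NO_ASP", "DEAD")]), 1)
  # tunnel mortality: baseline hazard scaled by the pneumonia RR, rate scale
  expect_equal(unname(ap1["DEAD"]), 1 - (1 - p$mortality[10])^p$rr_death_ap)
  expect_error(build_transition_row("LIMBO", 1, params = p), "unknown state")
})

test_that("pneumonia onset probability matches the hazard-scale conversion", {
  p <- base_dynamic()
  row <- build_transition_row("DYS_ASP", 20, "comparator", p)
  onset <- 1 - exp(-0.004036 * 8.27)   # 0.032827
  expect_equal(unname(row["AP1_ASP"]), (1 - p$mortality[20]) * onset,
               tolerance = 1e-9)
})

test_that("zero hazards freeze every non-tunnel state", {
  p <- dynamic_params(baseline_ap_ir_weekly = 0, deterioration_weekly = 0,
                      resolution = rep(0, 8), mortality = rep(0, 8),
                      u_no_dysphagia = 0.5, monitoring_weeks = integer(0),
                      horizon_weeks = 8)
  for (s in c("NO_DYS", "DYS_NO_ASP", "DYS_ASP")) {
    row <- build_transition_row(s, 3, params = p)
    expect_equal(unname(row[s]), 1)
  }
})

test_that("cohort occupancy follows closed forms in special cases", {
  # constant resolution only: dysphagia occupancy decays geometrically
  p <- dynamic_params(baseline_ap_ir_weekly = 0, deterioration_weekly = 0,
                      resolution = rep(0.05, 20), mortality = rep(0, 20),
                      u_no_dysphagia = 0.5, monitoring_weeks = integer(0),
                      horizon_weeks = 20)
  tr <- run_cohort("comparator", p)
  expect_equal(unname(tr[, "DYS_ASP"]), 0.95^(0:20), tolerance = 1e-12)

  # mortality only: the alive fraction equals the product of weekly survival
  m <- mortality_schedule(0.046, 0.0096, 0.0024, 52)
  pm <- dynamic_params(baseline_ap_ir_weekly = 0, deterioration_weekly = 0,
                       resolution = rep(0, 52), mortality = m,
                       u_no_dysphagia = 0.5, horizon_weeks = 52)
  trm <- run_cohort("intervention", pm)
  expect_equal(1 - unname(trm[53, "DEAD"]), prod(1 - m), tolerance = 1e-12)

  # zero horizon: the trace is the initial occupancy
  p0 <- dynamic_params(resolution = numeric(0), mortality = numeric(0),
                       u_no_dysphagia = 0.5, monitoring_weeks = integer(0),
                       horizon_weeks = 0)
  tr0 <- run_cohort("comparator", p0)
  expect_equal(nrow(tr0), 1)
  expect_equal(unname(tr0[1, "DYS_ASP"]), 1)
})

test_that("occupancy is conserved and dead is monotone on random configurations", {
  set.seed(51)
  for (i in 1:12) {
    p <- random_dynamic_params()
    for (arm in c("intervention", "comparator")) {
      tr <- run_cohort(arm, p)
      expect_equal(unname(rowSums(tr)), rep(1, nrow(tr)), tolerance = 1e-10)
      expect_true(all(tr >= -1e-12 & tr <= 1 + 1e-12))
      expect_true(all(diff(tr[, "DEAD"]) >= -1e-12))
    }
  }
})

test_that("accrual handles degenerate traces", {
  # immediate death: no QALYs, no costs
  h <- 4
  p <- dynamic_params(resolution = rep(0, h), mortality = rep(1, h),
                      u_no_dysphagia = 0.5, monitoring_weeks = 1:h,
                      horizon_weeks = h)
  r <- accrue(run_cohort("intervention", p), "intervention", p)
  expect_equal(r$qaly, 0)
  expect_equal(r$cost_monitoring, 0)
  expect_equal(r$cost_dysphagia_treatment, 0)

  # no events at all: a full year in dysphagia at utility 0.37
  p2 <- dynamic_params(baseline_ap_ir_weekly = 0, deterioration_weekly = 0,
                       resolution = rep(0, 52), mortality = rep(0, 52),
                       u_no_dysphagia = 0.5, monitoring_weeks = integer(0),
                       horizon_weeks = 52)
  r2 <- accrue(run_cohort("intervention", p2), "intervention", p2)
  expect_equal(r2$qaly, 0.37)
  expect_equal(r2$cost_dysphagia_treatment, 52 * p2$nutilis_weekly_cost)
  expect_equal(r2$cost_ap_treatment, 0)
  # the comparator accrues no thickener cost
  rc <- accrue(run_cohort("comparator", p2), "comparator", p2)
  expect_equal(rc$cost_dysphagia_treatment, 0)
})

test_that("monitoring cost is bounded by the visit schedule", {
  p <- base_dynamic()
  for (arm in c("intervention", "comparator")) {
    r <- accrue(run_cohort(arm, p), arm, p)
    expect_lte(r$cost_monitoring,
               length(p$monitoring_weeks) * p$cost_monitoring_visit)
    expect_gte(r$cost_monitoring, 0)
  }
})

test_that("dynamic model converges to the static model when degenerate", {
  # 8-week horizon, no death/resolution/deterioration, weekly pneumonia
  # hazards calibrated to the static arms' expected episode counts
  dyn <- dynamic_cea(equivalence_params())
  sta <- static_cea(static_params())
  for (arm in c("intervention", "comparator")) {
    expect_equal(dyn[[arm]]$qaly, sta[[arm]]$qaly, tolerance = 0.01)
    expect_equal(dyn[[arm]]$cost_total, sta[[arm]]$cost_total,
                 tolerance = 0.01)
  }
  expect_equal(dyn$icur, sta$icur, tolerance = 0.01)
})

test_that("tunnel survivors re-enter the at-risk pool (repeat episodes)", {
  # with the hazard set from the first-episode cumulative risk, expected
  # episodes exceed that risk by exactly the renewal-predicted repeat mass
  p8 <- 10 / 82
  q <- 1 - (1 - p8)^(1 / 8)
  pars <- dynamic_params(
    baseline_ap_ir_weekly = 1, rr_ap_no_asp = 1e-12, rr_ap_asp = -log(1 - q),
    deterioration_weekly = 0, resolution = rep(0, 8), mortality = rep(0, 8),
    u_no_dysphagia = 0.5, monitoring_weeks = integer(0), horizon_weeks = 8)
  res <- accrue(run_cohort("comparator", pars), "comparator", pars)
  episodes <- res$cost_ap_treatment / pars$cost_ap_episode
  expect_equal(episodes, expected_ap_episodes(q, 8), tolerance = 1e-10)
  expect_gt(episodes, p8)
})

test_that("the intervention arm cannot lose QALYs under the stated orderings", {
  set.seed(61)
  for (i in 1:10) {
    p <- random_dynamic_params()   # u_dys_no_asp >= u_dys_asp by construction
    if (p$rr_ap_no_asp > p$rr_ap_asp) next
    cmp <- dynamic_cea(p)
    expect_gte(cmp$intervention$qaly, cmp$comparator$qaly - 1e-12)
  }
})

test_that("symmetric arms give zero incremental QALY and an undefined ICUR", {
  h <- 12
  p <- dynamic_params(rr_ap_no_asp = 3, rr_ap_asp = 3,
                      deterioration_weekly = 0,
                      resolution = rep(0.03, h),
                      mortality = rep(0.01, h),
                      u_no_dysphagia = 0.5, u_dys_no_asp = 0.25,
                      u_dys_asp = 0.25, monitoring_weeks = integer(0),
                      horizon_weeks = h)
  cmp <- dynamic_cea(p)
  expect_equal(cmp$delta_qaly, 0, tolerance = 1e-12)
  expect_true(is.na(cmp$icur))
})

test_that("traces tidy into long week-state-occupancy tables", {
  p <- base_dynamic()
  tr <- run_cohort("comparator", p)
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 53 * 8)
  expect_equal(sort(unique(df$state)), sort(markov_states()))
  expect_equal(sum(df$occupancy[df$week == 52]), 1, tolerance = 1e-10)
})
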