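# Parameter-estimation toolkit: rate conversions, pooled rates, relative
# risks, distribution back-calculation, resolution calibration, mortality
# schedules. These feed the static and dynamic cost-utility engines.

#' Convert a cumulative risk to a weekly incidence rate
#'
#' Under a constant-hazard (exponential) assumption, a cumulative risk `CR`
#' observed over `T` weeks of follow-up corresponds to the weekly incidence
#' rate `IR = -ln(1 - CR) / T`.
#'
#' @param cumulative_risk Cumulative risk of the event over the follow-up,
#'   in `[0, 1)`.
#' @param followup_weeks Follow-up duration in weeks (> 0).
#' @return Weekly incidence rate (per-week hazard), non-negative. Vectorised.
#' @examples
#' incidence_rate_from_cumulative(0.122, 8)
#' @export
incidence_rate_from_cumulative <- function(cumulative_risk, followup_weeks) {
  stopifnot(is.numeric(cumulative_risk), is.numeric(followup_weeks))
  if (any(cumulative_risk < 0 | cumulative_risk >= 1)) {
    stop("`cumulative_risk` must lie in [0, 1): the rate is undefined at CR >= 1.",
         call. = FALSE)
  }
  if (any(followup_weeks <= 0)) {
    stop("`followup_weeks` must be positive.", call. = FALSE)
  }
  -log1p(-cumulative_risk) / followup_weeks
}

#' Pool weekly incidence rates across studies, weighting by sample size
#'
#' Each study's cumulative risk is first converted to a weekly incidence rate
#' ([incidence_rate_from_cumulative()]); the per-study rates are then averaged
#' with weights proportional to the number of patients.
#'
#' @param studies A data.frame with columns `cumulative_risk`,
#'   `followup_weeks` and `n_patients` (one row per study), e.g. as returned
#'   by [read_studies()].
#' @return The pooled weekly incidence rate (scalar).
#' @seealso [read_studies()] to build the study table from event counts.
#' @export
pooled_incidence_rate <- function(studies) {
  if (!is.data.frame(studies) || nrow(studies) == 0L) {
    stop("`studies` must be a non-empty data.frame.", call. = FALSE)
  }
  required <- c("cumulative_risk", "followup_weeks", "n_patients")
  missing <- setdiff(required, names(studies))
  if (length(missing)) {
    stop("`studies` is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(studies$n_patients <= 0)) {
    stop("`n_patients` must be positive for every study.", call. = FALSE)
  }
  ir <- incidence_rate_from_cumulative(studies$cumulative_risk,
                                       studies$followup_weeks)
  stats::weighted.mean(ir, studies$n_patients)
}

#' Read a study table for pooled incidence-rate estimation
#'
#' Reads a CSV with columns `label`, `events`, `n`, `followup_weeks` and
#' derives per-study cumulative risks.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with columns `label`, `events`, `n_patients`,
#'   `followup_weeks`, `cumulative_risk`.
#' @export
read_studies <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("label", "events", "n", "followup_weeks")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("study CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$events < 0 | x$events > x$n)) {
    stop("`events` must satisfy 0 <= events <= n in every row.", call. = FALSE)
  }
  data.frame(
    label = x$label,
    events = x$events,
    n_patients = x$n,
    followup_weeks = x$followup_weeks,
    cumulative_risk = x$events / x$n
  )
}

#' Relative risk from a 2x2 table with a log-normal confidence interval
#'
#' Point estimate `(a/n1) / (b/n2)` with the Katz confidence interval on the
#' log scale, `SE(log RR) = sqrt(1/a - 1/n1 + 1/b - 1/n2)`.
#'
#' @param events_exposed,n_exposed Events and group size in the exposed group.
#' @param events_reference,n_reference Events and group size in the reference
#'   group. `events_reference` must be positive for the estimate to exist.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `rr_estimate`: a list with `point`, `ci_low`,
#'   `ci_high`, `conf_level` and `reliable` (FALSE when the exposed group has
#'   zero events, in which case the point is 0 and the interval degenerate).
#' @examples
#' relative_risk(24, 83, 5, 143)  # aspirating dysphagia vs no dysphagia
#' @export
relative_risk <- function(events_exposed, n_exposed,
                          events_reference, n_reference,
                          conf_level = 0.95) {
  stopifnot(n_exposed > 0, n_reference > 0,
            events_exposed >= 0, events_exposed <= n_exposed,
            events_reference >= 0, events_reference <= n_reference,
            conf_level > 0, conf_level < 1)
  if (events_reference == 0) {
    stop("relative risk is undefined when the reference group has zero events.",
         call. = FALSE)
  }
  point <- (events_exposed / n_exposed) / (events_reference / n_reference)
  if (events_exposed == 0) {
    out <- list(point = 0, ci_low = 0, ci_high = 0,
                conf_level = conf_level, reliable = FALSE)
    class(out) <- "rr_estimate"
    return(out)
  }
  se <- sqrt(1 / events_exposed - 1 / n_exposed +
             1 / events_reference - 1 / n_reference)
  z <- stats::qnorm((1 + conf_level) / 2)
  out <- list(point = point,
              ci_low = exp(log(point) - z * se),
              ci_high = exp(log(point) + z * se),
              conf_level = conf_level,
              reliable = TRUE)
  class(out) <- "rr_estimate"
  out
}

#' @export
print.rr_estimate <- function(x, ...) {
  cat(sprintf("RR %.2f (%.0f%% CI %.2f; %.2f)%s\n",
              x$point, 100 * x$conf_level, x$ci_low, x$ci_high,
              if (x$reliable) "" else " [unreliable: zero exposed events]"))
  invisible(x)
}

#' Convert a weekly rate (optionally scaled by a relative risk) to a
#' per-cycle transition probability
#'
#' Applies the relative risk on the hazard scale:
#' `p = 1 - exp(-rate * rr)`.
#'
#' @param ir_weekly Weekly incidence rate (>= 0).
#' @param rr Relative risk multiplier (> 0), default 1.
#' @return Transition probability in `[0, 1)`. Vectorised.
#' @export
weekly_probability <- function(ir_weekly, rr = 1) {
  if (any(ir_weekly < 0)) stop("`ir_weekly` must be non-negative.", call. = FALSE)
  if (any(rr <= 0)) stop("`rr` must be positive.", call. = FALSE)
  -expm1(-ir_weekly * rr)
}

#' Back-calculate a standard deviation from a symmetric confidence interval
#'
#' `SD = (high - low) / (2 z)`, with `z` the standard-normal quantile at
#' `(1 + level)/2`. Used to recover sampling SDs for probabilistic sensitivity
#' analysis when a source reports only an interval.
#'
#' @param low,high Interval bounds (`low <= high`).
#' @param conf_level Confidence level of the interval, default 0.95.
#' @return Standard deviation (scalar, >= 0).
#' @export
sd_from_interval <- function(low, high, conf_level = 0.95) {
  stopifnot(conf_level > 0, conf_level < 1)
  if (any(low > high)) stop("`low` must not exceed `high`.", call. = FALSE)
  (high - low) / (2 * stats::qnorm((1 + conf_level) / 2))
}

#' Beta shape parameters from a mean and standard deviation
#'
#' Method of moments: with `k = mean (1 - mean) / sd^2 - 1`,
#' `shape1 = mean k` and `shape2 = (1 - mean) k`.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation with `sd^2 < mean (1 - mean)`.
#' @return Named numeric vector `c(shape1, shape2)`.
#' @export
beta_from_moments <- function(mean, sd) {
  stopifnot(mean > 0, mean < 1, sd > 0)
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("variance too large for a beta distribution: need sd^2 < mean*(1-mean).",
         call. = FALSE)
  }
  k <- mean * (1 - mean) / v - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Gamma shape and rate from a mean and standard deviation
#'
#' Method of moments: `shape = mean^2 / sd^2`, `rate = mean / sd^2`.
#'
#' @param mean Positive mean.
#' @param sd Positive standard deviation.
#' @return Named numeric vector `c(shape, rate)`.
#' @export
gamma_from_moments <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  c(shape = mean^2 / sd^2, rate = mean / sd^2)
}

#' Log-normal parameters from a point estimate and confidence interval
#'
#' For ratio parameters (relative risks) reported as `point (low; high)`:
#' `meanlog = log(point)`, `sdlog = (log(high) - log(low)) / (2 z)`.
#'
#' @param point Point estimate (> 0).
#' @param low,high Confidence bounds (0 < low <= high).
#' @param conf_level Confidence level, default 0.95.
#' @return Named numeric vector `c(meanlog, sdlog)`.
#' @export
lognormal_from_ci <- function(point, low, high, conf_level = 0.95) {
  stopifnot(point > 0, low > 0, low <= high)
  z <- stats::qnorm((1 + conf_level) / 2)
  c(meanlog = log(point), sdlog = (log(high) - log(low)) / (2 * z))
}

#' Calibrate a weekly dysphagia-resolution schedule to prevalence anchors
#'
#' Dysphagia prevalence among survivors is linearly interpolated between the
#' anchor points on a weekly grid (week `w` corresponds to day `7 w`), and the
#' weekly probability of resolution at week `w` is the one-step ratio
#' `1 - prev(w)/prev(w - 1)`, clamped to `[0, 1]`. An anchor of zero
#' prevalence at day 365 is appended when absent, encoding the assumption that
#' no patient still has dysphagia after one year.
#'
#' @param points A data.frame with columns `time_days` (non-negative, sorted
#'   increasing, starting at 0 with fraction 1) and `fraction_with_dysphagia`
#'   (non-increasing probabilities).
#' @param horizon_weeks Number of model weeks, default 52.
#' @return Numeric vector of length `horizon_weeks`: the weekly resolution
#'   probabilities (class `resolution_schedule`).
#' @seealso [simulate_prevalence()] for the inverse (schedule to anchors).
#' @export
calibrate_resolution <- function(points, horizon_weeks = 52) {
  stopifnot(is.data.frame(points),
            all(c("time_days", "fraction_with_dysphagia") %in% names(points)))
  d <- points$time_days
  f <- points$fraction_with_dysphagia
  if (any(f < 0 | f > 1)) {
    stop("`fraction_with_dysphagia` must lie in [0, 1].", call. = FALSE)
  }
  if (is.unsorted(d, strictly = TRUE)) {
    stop("`time_days` must be strictly increasing.", call. = FALSE)
  }
  if (d[1] != 0 || f[1] != 1) {
    stop("calibration anchors must start at day 0 with fraction 1 ",
         "(the modelled cohort enters with dysphagia).", call. = FALSE)
  }
  if (any(diff(f) > 0)) {
    stop("prevalence anchors must be non-increasing in time.", call. = FALSE)
  }
  if (max(d) < 365) {
    d <- c(d, 365)
    f <- c(f, 0)
  }
  grid_days <- pmin(7 * (0:horizon_weeks), max(d))
  prev <- stats::approx(d, f, xout = grid_days, rule = 2)$y
  res <- ifelse(prev[-length(prev)] > 0,
                1 - prev[-1] / prev[-length(prev)],
                0)
  res <- pmin(pmax(res, 0), 1)
  structure(res, class = "resolution_schedule")
}

#' Piecewise-constant weekly mortality schedule
#'
#' Post-stroke weekly death probabilities with three levels: the first 30 days
#' (weeks 1-4), days 31-90 (weeks 5-13), and the remainder of the first year
#' (weeks 14 onward).
#'
#' @param p30 Weekly death probability in the first 30 days (default 4.60%).
#' @param p90 Weekly death probability days 31-90 (default 0.96%).
#' @param p_rest Weekly death probability thereafter (default 0.24%).
#' @param horizon_weeks Schedule length, default 52. Horizons shorter than 14
#'   weeks truncate the schedule with a warning.
#' @return Numeric vector of length `horizon_weeks` of weekly death
#'   probabilities.
#' @export
mortality_schedule <- function(p30 = 0.046, p90 = 0.0096, p_rest = 0.0024,
                               horizon_weeks = 52) {
  p <- c(p30, p90, p_rest)
  if (any(p < 0 | p > 1)) {
    stop("mortality probabilities must lie in [0, 1].", call. = FALSE)
  }
  stopifnot(horizon_weeks >= 1)
  full <- c(rep(p30, 4), rep(p90, 9), rep(p_rest, max(horizon_weeks - 13, 0)))
  if (horizon_weeks < 14) {
    warning("horizon shorter than 14 weeks: mortality schedule truncated.",
            call. = FALSE)
  }
  full[seq_len(horizon_weeks)]
}

#' Fit a logarithmic curve to cumulative-mortality time points
#'
#' Ordinary least squares of cumulative mortality on `ln(t)`:
#' `M(t) = a ln(t) + b`. Used by the mortality scenario analysis as an
#' alternative to the piecewise-constant schedule.
#'
#' @param time_days Observation times in days (> 0), at least two.
#' @param cumulative_mortality Cumulative mortality at each time.
#' @return A list with `a` (slope), `b` (intercept) and `r_squared`.
#' @export
fit_log_survival <- function(time_days, cumulative_mortality) {
  stopifnot(length(time_days) == length(cumulative_mortality))
  if (length(time_days) < 2) {
    stop("at least two time points are required.", call. = FALSE)
  }
  if (any(time_days <= 0)) stop("`time_days` must be positive.", call. = FALSE)
  fit <- stats::lm(cumulative_mortality ~ log(time_days))
  ss_tot <- sum((cumulative_mortality - mean(cumulative_mortality))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  list(a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Weekly mortality schedule from a fitted logarithmic cumulative curve
#'
#' Converts the fitted cumulative mortality `M(t) = a ln(t) + b` into
#' conditional weekly death probabilities
#' `p_w = (M(7w) - M(7(w-1))) / (1 - M(7(w-1)))`, clamped to `[0, 1]`.
#'
#' @param fit A list with `a` and `b`, as returned by [fit_log_survival()].
#' @param horizon_weeks Schedule length, default 52.
#' @return Numeric vector of weekly death probabilities.
#' @export
log_fit_mortality_schedule <- function(fit, horizon_weeks = 52) {
  stopifnot(is.list(fit), all(c("a", "b") %in% names(fit)))
  m <- function(t) pmin(pmax(fit$a * log(pmax(t, 1)) + fit$b, 0), 1)
  w <- seq_len(horizon_weeks)
  m_prev <- m(7 * (w - 1))
  m_now <- m(7 * w)
  p <- ifelse(m_prev < 1, (m_now - m_prev) / (1 - m_prev), 1)
  pmin(pmax(p, 0), 1)
}
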