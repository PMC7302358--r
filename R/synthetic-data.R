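# Fixture and simulators: the shipped base-case configuration, and
# seed-reproducible generators matching the statistical structure the
# estimation stage assumes (binomial 2x2 cohorts; prevalence trajectories
# induced by a weekly resolution schedule).

#' The shipped base-case configuration
#'
#' Loads the canonical YAML fixture bundled with the package: every
#' main-source base-case parameter of the static and dynamic models, plus
#' flagged synthetic placeholders for the fields whose source data are
#' supplementary-only (dysphagia-prevalence anchors, utility of resolved
#' dysphagia, PSA cost SD fraction) — see `assumed_fields` in the returned
#' object.
#'
#' @return A `model_config` (see [load_config()]).
#' @examples
#' cfg <- base_case_fixture()
#' static_cea(cfg$static)
#' @export
base_case_fixture <- function() {
  load_config(system.file("extdata", "base_case.yaml",
                          package = "dysphagiaCE", mustWork = TRUE))
}

#' Simulate a 2x2 cohort outcome table
#'
#' Binomial event counts in an exposed and a reference group, for
#' parameter-recovery testing of [relative_risk()].
#'
#' @param p_exposed,p_reference True event probabilities.
#' @param n_exposed,n_reference Group sizes (> 0).
#' @param seed Integer seed; same seed, same table.
#' @return A list with `events_exposed`, `n_exposed`, `events_reference`,
#'   `n_reference`.
#' @export
simulate_two_by_two <- function(p_exposed, p_reference,
                                n_exposed, n_reference, seed) {
  stopifnot(p_exposed >= 0, p_exposed <= 1, p_reference >= 0, p_reference <= 1,
            n_exposed > 0, n_reference > 0)
  set.seed(seed)
  list(events_exposed = stats::rbinom(1, n_exposed, p_exposed),
       n_exposed = n_exposed,
       events_reference = stats::rbinom(1, n_reference, p_reference),
       n_reference = n_reference)
}

#' Dysphagia prevalence implied by a weekly resolution schedule
#'
#' Survival-to-dysphagia under a weekly resolution schedule, read off at
#' arbitrary anchor days (linear interpolation within weeks). In
#' deterministic mode (default) the exact fractions are returned; with
#' `n_patients` set, binomial sampling noise at that cohort size is added.
#' Mortality is not simulated: this is the prevalence among patients still
#' alive, which is what resolution calibration conditions on.
#'
#' @param schedule Weekly resolution probabilities
#'   (e.g. [calibrate_resolution()] output).
#' @param anchor_days Days at which to report prevalence; must lie within
#'   the schedule's horizon (`7 * length(schedule)` days).
#' @param n_patients Optional cohort size for stochastic mode.
#' @param seed Integer seed, required in stochastic mode.
#' @return A data.frame with columns `time_days`, `fraction_with_dysphagia`.
#' @export
simulate_prevalence <- function(schedule, anchor_days,
                                n_patients = NULL, seed = NULL) {
  schedule <- as.numeric(schedule)
  stopifnot(all(schedule >= 0 & schedule <= 1), all(anchor_days >= 0))
  horizon_days <- 7 * length(schedule)
  if (any(anchor_days > horizon_days)) {
    stop("anchor day beyond the schedule horizon (", horizon_days, " days).",
         call. = FALSE)
  }
  prev_weekly <- c(1, cumprod(1 - schedule))
  frac <- stats::approx(x = 7 * (0:length(schedule)), y = prev_weekly,
                        xout = anchor_days)$y
  if (!is.null(n_patients)) {
    stopifnot(n_patients > 0)
    if (is.null(seed)) stop("stochastic mode requires `seed`.", call. = FALSE)
    set.seed(seed)
    frac <- stats::rbinom(length(frac), n_patients, frac) / n_patients
  }
  data.frame(time_days = anchor_days, fraction_with_dysphagia = frac)
}
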