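# Weekly-cycle Markov cohort model over one year. States: no dysphagia,
# dysphagia without/with fluid aspiration, a 2-week aspiration-pneumonia
# tunnel (tagged by the originating dysphagia state, so patients return
# where they came from), and death. The transition structure is shared by
# both arms; the arms differ in their starting state (the thickener removes
# fluid aspiration) and in thickener cost accrual.

#' Health states of the dynamic model
#'
#' State codes, in column order of a [run_cohort()] trace:
#' `NO_DYS` (dysphagia resolved), `DYS_NO_ASP` / `DYS_ASP` (dysphagia without
#' / with fluid aspiration), `AP1_*` / `AP2_*` (first / second week of an
#' aspiration-pneumonia episode, tagged by originating dysphagia state) and
#' the absorbing `DEAD`.
#'
#' @return Character vector of the eight state codes.
#' @export
markov_states <- function() {
  c("NO_DYS", "DYS_NO_ASP", "DYS_ASP",
    "AP1_NO_ASP", "AP2_NO_ASP", "AP1_ASP", "AP2_ASP", "DEAD")
}

DYSPHAGIA_STATES <- c("DYS_NO_ASP", "DYS_ASP",
                      "AP1_NO_ASP", "AP2_NO_ASP", "AP1_ASP", "AP2_ASP")

#' Parameters of the dynamic (Markov) cost-utility model
#'
#' Defaults are the base case: weekly aspiration-pneumonia (AP) incidence
#' rate 0.4036% in patients without dysphagia, relative risks 2.77
#' (dysphagia without aspiration) and 8.27 (with aspiration), AP mortality
#' relative risk 2.99, weekly deterioration (onset of aspirations) 0.11%,
#' the three-level weekly mortality schedule 4.60% / 0.96% / 0.24%, utilities
#' 0.37 / 0.15 with AP disutility 0.13, AP episode cost 1924 PLN charged on
#' tunnel entry, monitoring visits (186 PLN) at weeks 1, 4, 12, 26, 39 and
#' 52 for patients still in a dysphagia state, and thickener dosing
#' 37.96 g/day at 77.05 PLN per 175 g tin in the intervention arm.
#'
#' The dysphagia-resolution schedule and the utility of resolved dysphagia
#' have no single published base value; supply them explicitly or take the
#' shipped fixture's flagged placeholder values (see [base_case_fixture()]).
#'
#' @param baseline_ap_ir_weekly Weekly AP incidence rate without dysphagia.
#' @param rr_ap_no_asp,rr_ap_asp AP relative risks for dysphagia without /
#'   with aspiration.
#' @param rr_death_ap Mortality relative risk during an AP episode (applied
#'   on the hazard scale).
#' @param deterioration_weekly Weekly probability that a non-aspirating
#'   patient starts aspirating.
#' @param resolution Weekly resolution probabilities, length `horizon_weeks`
#'   (see [calibrate_resolution()]).
#' @param mortality Weekly death probabilities, length `horizon_weeks`
#'   (see [mortality_schedule()]).
#' @param u_no_dysphagia,u_dys_no_asp,u_dys_asp State utilities.
#' @param du_ap Utility decrement while in the AP tunnel.
#' @param ap_tunnel_weeks AP episode length in weeks (fixed at 2 by the
#'   tunnel structure; retained for reporting).
#' @param cost_ap_episode,cost_monitoring_visit Unit costs.
#' @param monitoring_weeks Integer vector of monitoring weeks within the
#'   horizon.
#' @param nutilis_daily_g,tin_g,tin_price Thickener dosing and pricing;
#'   the weekly cost `daily_g * 7 / tin_g * tin_price` accrues per week of
#'   dysphagia-state occupancy in the intervention arm.
#' @param horizon_weeks Model horizon, default 52.
#' @return An object of class `dynamic_params` (a validated list with the
#'   derived `nutilis_weekly_cost`).
#' @export
dynamic_params <- function(baseline_ap_ir_weekly = 0.004036,
                           rr_ap_no_asp = 2.77,
                           rr_ap_asp = 8.27,
                           rr_death_ap = 2.99,
                           deterioration_weekly = 0.0011,
                           resolution,
                           mortality = mortality_schedule(horizon_weeks = horizon_weeks),
                           u_no_dysphagia,
                           u_dys_no_asp = 0.37,
                           u_dys_asp = 0.15,
                           du_ap = 0.13,
                           ap_tunnel_weeks = 2,
                           cost_ap_episode = 1924,
                           cost_monitoring_visit = 186,
                           monitoring_weeks = c(1, 4, 12, 26, 39, 52),
                           nutilis_daily_g = 37.96,
                           tin_g = 175,
                           tin_price = 77.05,
                           horizon_weeks = 52) {
  p <- list(baseline_ap_ir_weekly = baseline_ap_ir_weekly,
            rr_ap_no_asp = rr_ap_no_asp, rr_ap_asp = rr_ap_asp,
            rr_death_ap = rr_death_ap,
            deterioration_weekly = deterioration_weekly,
            resolution = as.numeric(resolution),
            mortality = as.numeric(mortality),
            u_no_dysphagia = u_no_dysphagia,
            u_dys_no_asp = u_dys_no_asp, u_dys_asp = u_dys_asp,
            du_ap = du_ap, ap_tunnel_weeks = ap_tunnel_weeks,
            cost_ap_episode = cost_ap_episode,
            cost_monitoring_visit = cost_monitoring_visit,
            monitoring_weeks = as.integer(monitoring_weeks),
            nutilis_daily_g = nutilis_daily_g, tin_g = tin_g,
            tin_price = tin_price,
            nutilis_weekly_cost = nutilis_daily_g * 7 / tin_g * tin_price,
            horizon_weeks = as.integer(horizon_weeks))
  validate_dynamic_params(p)
}

validate_dynamic_params <- function(p) {
  h <- p$horizon_weeks
  stopifnot(h >= 0)
  if (p$baseline_ap_ir_weekly < 0) {
    stop("`baseline_ap_ir_weekly` must be non-negative.", call. = FALSE)
  }
  for (nm in c("rr_ap_no_asp", "rr_ap_asp", "rr_death_ap")) {
    if (p[[nm]] <= 0) stop(sprintf("`%s` must be positive.", nm), call. = FALSE)
  }
  for (nm in c("deterioration_weekly", "u_no_dysphagia", "u_dys_no_asp",
               "u_dys_asp", "du_ap")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop(sprintf("`%s` must lie in [0, 1].", nm), call. = FALSE)
    }
  }
  for (nm in c("resolution", "mortality")) {
    if (length(p[[nm]]) != h) {
      stop(sprintf("`%s` must have length horizon_weeks (%d), got %d.",
                   nm, h, length(p[[nm]])), call. = FALSE)
    }
    if (any(p[[nm]] < 0 | p[[nm]] > 1)) {
      stop(sprintf("`%s` entries must lie in [0, 1].", nm), call. = FALSE)
    }
  }
  if (length(p$monitoring_weeks) &&
      (any(p$monitoring_weeks < 1) || any(p$monitoring_weeks > h))) {
    stop("`monitoring_weeks` must lie within 1..horizon_weeks.", call. = FALSE)
  }
  for (nm in c("cost_ap_episode", "cost_monitoring_visit", "nutilis_daily_g",
               "tin_price")) {
    if (p[[nm]] < 0) stop(sprintf("`%s` must be non-negative.", nm), call. = FALSE)
  }
  if (p$tin_g <= 0) stop("`tin_g` must be positive.", call. = FALSE)
  structure(p, class = "dynamic_params")
}

#' Transition probabilities out of one state at one cycle
#'
#' Competing risks are applied multiplicatively in the order death, AP onset,
#' then resolution/deterioration among event-free survivors. In the AP tunnel
#' the weekly death probability is the baseline hazard scaled by the AP
#' mortality relative risk on the rate scale
#' (`1 - (1 - p_death)^rr_death_ap`), capped at 1; tunnel patients otherwise
#' progress week 1 to week 2 and then return to their originating dysphagia
#' state (resolution and deterioration are suspended during the episode).
#'
#' @param state One of [markov_states()].
#' @param week Cycle index in `1..horizon_weeks`.
#' @param arm `"intervention"` or `"comparator"` (the transition structure is
#'   arm-independent; the argument is accepted for interface symmetry).
#' @param params A [dynamic_params()] object.
#' @return Named probability vector over the states, summing to 1.
#' @export
build_transition_row <- function(state, week,
                                 arm = c("intervention", "comparator"),
                                 params) {
  arm <- match.arg(arm)
  stopifnot(inherits(params, "dynamic_params"),
            week >= 1, week <= params$horizon_weeks)
  states <- markov_states()
  if (!state %in% states) stop("unknown state: ", state, call. = FALSE)
  row <- stats::setNames(numeric(length(states)), states)
  p_d <- params$mortality[week]
  res <- params$resolution[week]
  det <- params$deterioration_weekly
  ir <- params$baseline_ap_ir_weekly
  if (state == "DEAD") {
    row["DEAD"] <- 1
  } else if (state == "NO_DYS") {
    row["DEAD"] <- p_d
    row["NO_DYS"] <- 1 - p_d
  } else if (state == "DYS_NO_ASP") {
    p_ap <- weekly_probability(ir, params$rr_ap_no_asp)
    row["DEAD"] <- p_d
    row["AP1_NO_ASP"] <- (1 - p_d) * p_ap
    row["NO_DYS"] <- (1 - p_d) * (1 - p_ap) * res
    row["DYS_ASP"] <- (1 - p_d) * (1 - p_ap) * (1 - res) * det
    row["DYS_NO_ASP"] <- (1 - p_d) * (1 - p_ap) * (1 - res) * (1 - det)
  } else if (state == "DYS_ASP") {
    p_ap <- weekly_probability(ir, params$rr_ap_asp)
    row["DEAD"] <- p_d
    row["AP1_ASP"] <- (1 - p_d) * p_ap
    row["NO_DYS"] <- (1 - p_d) * (1 - p_ap) * res
    row["DYS_ASP"] <- (1 - p_d) * (1 - p_ap) * (1 - res)
  } else {
    # AP tunnel: death at RR-scaled hazard, then forced progression.
    p_d_ap <- min(1 - (1 - p_d)^params$rr_death_ap, 1)
    origin <- if (grepl("NO_ASP$", state)) "DYS_NO_ASP" else "DYS_ASP"
    succ <- switch(state,
                   AP1_NO_ASP = "AP2_NO_ASP", AP1_ASP = "AP2_ASP",
                   AP2_NO_ASP = origin, AP2_ASP = origin)
    row["DEAD"] <- p_d_ap
    row[succ] <- 1 - p_d_ap
  }
  row
}

# Full transition matrix for one cycle (arm-independent).
transition_matrix <- function(week, params) {
  states <- markov_states()
  t(vapply(states, build_transition_row, numeric(length(states)),
           week = week, params = params))
}

starting_occupancy <- function(arm) {
  states <- markov_states()
  occ <- stats::setNames(numeric(length(states)), states)
  occ[if (arm == "intervention") "DYS_NO_ASP" else "DYS_ASP"] <- 1
  occ
}

#' Run the weekly cohort simulation for one arm
#'
#' The modelled cohort (patients tolerating semisolids but aspirating
#' fluids) starts entirely in `DYS_ASP` under routine practice; under the
#' thickener it starts in `DYS_NO_ASP`, since the intervention is assumed to
#' remove fluid aspiration without affecting dysphagia duration. Occupancy is
#' propagated by matrix multiplication for `horizon_weeks` cycles; each row
#' is checked for stochasticity to 1e-9.
#'
#' @param arm `"intervention"` or `"comparator"`.
#' @param params A [dynamic_params()] object.
#' @return An object of class `cohort_trace`: a `(horizon_weeks + 1) x 8`
#'   matrix of state-occupancy fractions, rows `week0..weekH`.
#' @export
run_cohort <- function(arm = c("intervention", "comparator"), params) {
  arm <- match.arg(arm)
  stopifnot(inherits(params, "dynamic_params"))
  h <- params$horizon_weeks
  states <- markov_states()
  trace <- matrix(0, nrow = h + 1, ncol = length(states),
                  dimnames = list(paste0("week", 0:h), states))
  trace[1, ] <- starting_occupancy(arm)
  for (w in seq_len(h)) {
    tm <- transition_matrix(w, params)
    if (any(abs(rowSums(tm) - 1) > 1e-9)) {
      stop("transition matrix row failed stochasticity at week ", w,
           call. = FALSE)
    }
    trace[w + 1, ] <- trace[w, ] %*% tm
  }
  structure(trace, arm = arm, class = c("cohort_trace", "matrix", "array"))
}

#' Tidy a cohort trace
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return A long data.frame with columns `week`, `state`, `occupancy`.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  m <- unclass(x)
  data.frame(week = rep(0:(nrow(m) - 1), times = ncol(m)),
             state = rep(colnames(m), each = nrow(m)),
             occupancy = as.vector(m))
}

#' Accrue QALYs and costs over a cohort trace
#'
#' QALYs sum end-of-cycle occupancy times state utility over the horizon, in
#' units of 1/52 year per week, with no half-cycle correction and no
#' discounting; AP tunnel weeks carry the originating state's utility minus
#' the AP disutility, and death contributes zero. Costs: the weekly thickener
#' cost accrues over dysphagia-state occupancy (including the AP tunnel) in
#' the intervention arm only; the AP episode cost is charged once on entry
#' into the first tunnel week; monitoring is charged at the scheduled weeks
#' to patients currently in a dysphagia state, in both arms.
#'
#' @param trace A [run_cohort()] trace.
#' @param arm `"intervention"` or `"comparator"`.
#' @param params The [dynamic_params()] used to generate the trace.
#' @return An `arm_result` (as in the static model).
#' @export
accrue <- function(trace, arm = c("intervention", "comparator"), params) {
  arm <- match.arg(arm)
  stopifnot(inherits(params, "dynamic_params"),
            nrow(trace) == params$horizon_weeks + 1)
  h <- params$horizon_weeks
  states <- markov_states()
  u <- stats::setNames(numeric(length(states)), states)
  u["NO_DYS"] <- params$u_no_dysphagia
  u["DYS_NO_ASP"] <- params$u_dys_no_asp
  u["DYS_ASP"] <- params$u_dys_asp
  u[c("AP1_NO_ASP", "AP2_NO_ASP")] <- params$u_dys_no_asp - params$du_ap
  u[c("AP1_ASP", "AP2_ASP")] <- params$u_dys_asp - params$du_ap
  if (h == 0) return(new_arm_result(arm, 0, 0, 0, 0))

  occ <- unclass(trace)[-1, , drop = FALSE]  # rows = end of weeks 1..h
  qaly <- sum(occ %*% u) / 52

  dys_occ <- rowSums(occ[, DYSPHAGIA_STATES, drop = FALSE])
  cost_dys <- if (arm == "intervention") {
    params$nutilis_weekly_cost * sum(dys_occ)
  } else 0

  # AP entries: inflow into AP1_* at each cycle.
  entries <- 0
  for (w in seq_len(h)) {
    tm <- transition_matrix(w, params)
    inflow <- unclass(trace)[w, ] %*% tm[, c("AP1_NO_ASP", "AP1_ASP")]
    entries <- entries + sum(inflow)
  }
  cost_ap <- params$cost_ap_episode * entries

  cost_mon <- params$cost_monitoring_visit *
    sum(dys_occ[params$monitoring_weeks])

  new_arm_result(arm, qaly, cost_dys, cost_ap, cost_mon)
}

#' Cost-utility comparison for the dynamic model
#'
#' Runs both arms of the Markov cohort model and returns the incremental
#' comparison (same structure as [static_cea()]).
#'
#' @param params A [dynamic_params()] object.
#' @return An object of class `ce_comparison`.
#' @export
dynamic_cea <- function(params) {
  res_i <- accrue(run_cohort("intervention", params), "intervention", params)
  res_c <- accrue(run_cohort("comparator", params), "comparator", params)
  new_ce_comparison(res_i, res_c, model = "dynamic")
}
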