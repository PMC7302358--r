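# Closed-form static model: fixed 8-week dysphagia horizon, two arms
# (thickener vs routine clinical practice), aspiration pneumonia as a
# one-off 2-week event. Costs and QALYs are simple products -- no cohort
# simulation, no death, no monitoring.

#' Cost of a thickener course
#'
#' Product cost of thickening powder over a treatment course, allowing
#' fractional tins: `cost = daily_g * days / tin_g * tin_price`.
#'
#' @param daily_g Daily consumption in grams (base case 37.96 g/day).
#' @param days Course length in days.
#' @param tin_g Tin content in grams (base case 175 g).
#' @param tin_price Price per tin from the payer perspective (base case
#'   77.05 PLN).
#' @return Course cost in the same currency as `tin_price`.
#' @examples
#' nutilis_course_cost(37.96, 56, 175, 77.05)  # 8-week course, ~936 PLN
#' @export
nutilis_course_cost <- function(daily_g, days, tin_g, tin_price) {
  stopifnot(daily_g >= 0, days >= 0, tin_price >= 0)
  if (tin_g <= 0) stop("`tin_g` must be positive.", call. = FALSE)
  daily_g * days / tin_g * tin_price
}

#' Parameters of the static cost-utility model
#'
#' Constructs and validates the parameter set for the closed-form model.
#' Defaults are the base case: aspiration-pneumonia (AP) risks over the
#' 8-week horizon of 10/82 among aspirators and 1/57 among non-aspirators
#' (entered as exact fractions), utilities 0.15 (dysphagia with aspiration)
#' and 0.37 (without), AP disutility 0.13 over a 2-week episode, AP episode
#' cost 1924 PLN, and thickener dosing 37.96 g/day at 77.05 PLN per 175 g tin.
#'
#' @param dysphagia_weeks Fixed dysphagia duration in weeks (default 8).
#' @param ap_weeks AP episode duration in weeks (default 2).
#' @param p_ap_aspirators Probability of AP over the horizon among aspirating
#'   patients (comparator arm).
#' @param p_ap_non_aspirators Probability of AP among non-aspirating patients
#'   (intervention arm).
#' @param u_aspiration Utility of dysphagia with aspiration.
#' @param u_no_aspiration Utility of dysphagia without aspiration.
#' @param du_ap Utility decrement during an AP episode.
#' @param cost_ap_episode Cost of one AP episode (currency units).
#' @param nutilis_daily_g,tin_g,tin_price Thickener dosing and pricing.
#' @return An object of class `static_params` (a validated list).
#' @export
static_params <- function(dysphagia_weeks = 8,
                          ap_weeks = 2,
                          p_ap_aspirators = 10 / 82,
                          p_ap_non_aspirators = 1 / 57,
                          u_aspiration = 0.15,
                          u_no_aspiration = 0.37,
                          du_ap = 0.13,
                          cost_ap_episode = 1924,
                          nutilis_daily_g = 37.96,
                          tin_g = 175,
                          tin_price = 77.05) {
  p <- list(dysphagia_weeks = dysphagia_weeks, ap_weeks = ap_weeks,
            p_ap_aspirators = p_ap_aspirators,
            p_ap_non_aspirators = p_ap_non_aspirators,
            u_aspiration = u_aspiration, u_no_aspiration = u_no_aspiration,
            du_ap = du_ap, cost_ap_episode = cost_ap_episode,
            nutilis_daily_g = nutilis_daily_g, tin_g = tin_g,
            tin_price = tin_price)
  validate_static_params(p)
}

validate_static_params <- function(p) {
  probs <- c(p_ap_aspirators = p$p_ap_aspirators,
             p_ap_non_aspirators = p$p_ap_non_aspirators)
  for (nm in names(probs)) {
    if (probs[[nm]] < 0 || probs[[nm]] > 1) {
      stop(sprintf("`%s` must be a probability in [0, 1].", nm), call. = FALSE)
    }
  }
  for (nm in c("u_aspiration", "u_no_aspiration")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop(sprintf("`%s` must be a utility in [0, 1].", nm), call. = FALSE)
    }
  }
  if (p$du_ap < 0) stop("`du_ap` must be non-negative.", call. = FALSE)
  for (nm in c("cost_ap_episode", "nutilis_daily_g", "tin_price")) {
    if (p[[nm]] < 0) stop(sprintf("`%s` must be non-negative.", nm), call. = FALSE)
  }
  if (p$tin_g <= 0) stop("`tin_g` must be positive.", call. = FALSE)
  stopifnot(p$dysphagia_weeks >= 0, p$ap_weeks >= 0)
  structure(p, class = "static_params")
}

# Pure arithmetic core shared by static_arm() and the PSA fast path.
static_arm_values <- function(p, arm) {
  if (arm == "intervention") {
    p_ap <- p$p_ap_non_aspirators
    u <- p$u_no_aspiration
    c_dys <- nutilis_course_cost(p$nutilis_daily_g, 7 * p$dysphagia_weeks,
                                 p$tin_g, p$tin_price)
  } else {
    p_ap <- p$p_ap_aspirators
    u <- p$u_aspiration
    c_dys <- 0
  }
  c_ap <- p$cost_ap_episode * p_ap
  qaly <- u * p$dysphagia_weeks / 52 - p$du_ap * p$ap_weeks / 52 * p_ap
  list(qaly = qaly, cost_dysphagia_treatment = c_dys, cost_ap_treatment = c_ap)
}

#' Evaluate one arm of the static model
#'
#' Intervention arm: thickener course cost plus expected AP treatment cost;
#' QALYs at the no-aspiration utility minus the expected AP disutility.
#' Comparator arm (routine practice): the same structure at the aspirating
#' utility and AP risk, with zero dysphagia-treatment cost. Monitoring is not
#' costed in the static model.
#'
#' @param params A [static_params()] object.
#' @param arm `"intervention"` or `"comparator"`.
#' @return An object of class `arm_result`: a list with `arm`, `qaly`,
#'   `cost_total`, `cost_dysphagia_treatment`, `cost_ap_treatment`,
#'   `cost_monitoring`.
#' @export
static_arm <- function(params, arm = c("intervention", "comparator")) {
  stopifnot(inherits(params, "static_params"))
  arm <- match.arg(arm)
  v <- static_arm_values(params, arm)
  new_arm_result(arm, v$qaly, v$cost_dysphagia_treatment, v$cost_ap_treatment,
                 cost_monitoring = 0)
}

new_arm_result <- function(arm, qaly, cost_dys, cost_ap, cost_monitoring) {
  structure(list(arm = arm,
                 qaly = qaly,
                 cost_total = cost_dys + cost_ap + cost_monitoring,
                 cost_dysphagia_treatment = cost_dys,
                 cost_ap_treatment = cost_ap,
                 cost_monitoring = cost_monitoring),
            class = "arm_result")
}

new_ce_comparison <- function(intervention, comparator, model) {
  delta_cost <- intervention$cost_total - comparator$cost_total
  delta_qaly <- intervention$qaly - comparator$qaly
  if (delta_qaly == 0) {
    icur <- NA_real_
    dominance <- "undefined (zero incremental QALY)"
  } else {
    icur <- delta_cost / delta_qaly
    dominance <- if (delta_cost <= 0 && delta_qaly > 0) {
      "intervention dominant"
    } else if (delta_cost >= 0 && delta_qaly < 0) {
      "intervention dominated"
    } else {
      "none"
    }
  }
  structure(list(model = model,
                 intervention = intervention, comparator = comparator,
                 delta_cost = delta_cost, delta_qaly = delta_qaly,
                 icur = icur, dominance = dominance),
            class = "ce_comparison")
}

#' Cost-utility comparison for the static model
#'
#' Evaluates both arms and the incremental cost-utility ratio
#' `ICUR = (C_int - C_comp) / (QALY_int - QALY_comp)`. When the incremental
#' QALY is zero the ICUR is undefined and a dominance flag is reported
#' instead; negative-cost/positive-QALY combinations are flagged dominant.
#'
#' @param params A [static_params()] object.
#' @return An object of class `ce_comparison`.
#' @examples
#' static_cea(static_params())  # base case, ICUR ~ 21,400 PLN/QALY
#' @export
static_cea <- function(params) {
  new_ce_comparison(static_arm(params, "intervention"),
                    static_arm(params, "comparator"),
                    model = "static")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("%s arm: %.4f QALY, total cost %.2f\n", x$arm, x$qaly,
              x$cost_total))
  cat(sprintf("  dysphagia treatment %.2f | AP treatment %.2f | monitoring %.2f\n",
              x$cost_dysphagia_treatment, x$cost_ap_treatment,
              x$cost_monitoring))
  invisible(x)
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat(sprintf("Cost-utility comparison (%s model)\n", x$model))
  print(x$intervention)
  print(x$comparator)
  cat(sprintf("  incremental cost %.2f | incremental QALY %.5f\n",
              x$delta_cost, x$delta_qaly))
  if (is.na(x$icur)) {
    cat("  ICUR undefined:", x$dominance, "\n")
  } else {
    cat(sprintf("  ICUR %.0f per QALY%s\n", x$icur,
                if (x$dominance == "none") "" else paste0(" [", x$dominance, "]")))
  }
  invisible(x)
}

#' Tidy one-row summary of a cost-utility comparison
#'
#' @param x A `ce_comparison`.
#' @param ... Unused.
#' @return A one-row data.frame with per-arm QALYs/costs and increments.
#' @export
as.data.frame.ce_comparison <- function(x, ...) {
  data.frame(model = x$model,
             qaly_intervention = x$intervention$qaly,
             qaly_comparator = x$comparator$qaly,
             cost_intervention = x$intervention$cost_total,
             cost_comparator = x$comparator$cost_total,
             delta_cost = x$delta_cost,
             delta_qaly = x$delta_qaly,
             icur = x$icur,
             dominance = x$dominance)
}
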