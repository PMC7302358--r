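# Deterministic one-way (tornado) and scenario sensitivity analyses, and
# probabilistic sensitivity analysis with cost-effectiveness acceptability
# curves. All analyses re-evaluate the full model object; nothing is
# linearised.

#' Evaluate a cost-utility model from its parameter object
#'
#' Dispatches to [static_cea()] or [dynamic_cea()].
#'
#' @param params A [static_params()] or [dynamic_params()] object.
#' @return A `ce_comparison`.
#' @export
evaluate_cea <- function(params) UseMethod("evaluate_cea")

#' @export
evaluate_cea.static_params <- function(params) static_cea(params)

#' @export
evaluate_cea.dynamic_params <- function(params) dynamic_cea(params)

revalidate <- function(params) {
  if (inherits(params, "static_params")) validate_static_params(unclass(params))
  else validate_dynamic_params(unclass(params))
}

#' Replace one parameter in a model parameter object
#'
#' @param params A [static_params()] or [dynamic_params()] object.
#' @param parameter Field name.
#' @param value New value; the object is re-validated, so out-of-domain
#'   values raise the usual validation error.
#' @return The modified, re-validated parameter object.
#' @export
set_param <- function(params, parameter, value) {
  if (!parameter %in% names(params)) {
    stop("unknown parameter: `", parameter, "`", call. = FALSE)
  }
  params[[parameter]] <- value
  revalidate(params)
}

#' One-way parameter ranges for the static model
#'
#' The ranges varied in the deterministic and probabilistic analyses:
#' stated intervals for the utilities (0.135-0.165 for dysphagia with
#' aspiration; 0.32-0.42 without; 0.10-0.15 for the pneumonia disutility)
#' and exact (Clopper-Pearson) binomial confidence intervals for the two
#' aspiration-pneumonia risks, computed from their source counts.
#'
#' @param counts_aspirators,counts_non_aspirators Length-2 vectors
#'   `c(events, n)`; defaults 10/82 and 1/57.
#' @param conf_level Level for the binomial intervals, default 0.95.
#' @return A data.frame with columns `parameter`, `low`, `high`, `source`.
#' @export
static_ranges <- function(counts_aspirators = c(10, 82),
                          counts_non_aspirators = c(1, 57),
                          conf_level = 0.95) {
  ci_a <- stats::binom.test(counts_aspirators[1], counts_aspirators[2],
                            conf.level = conf_level)$conf.int
  ci_n <- stats::binom.test(counts_non_aspirators[1], counts_non_aspirators[2],
                            conf.level = conf_level)$conf.int
  data.frame(
    parameter = c("u_aspiration", "u_no_aspiration", "du_ap",
                  "p_ap_aspirators", "p_ap_non_aspirators"),
    low = c(0.135, 0.32, 0.10, ci_a[1], ci_n[1]),
    high = c(0.165, 0.42, 0.15, ci_a[2], ci_n[2]),
    source = c("stated", "ci", "stated", "binomial_ci", "binomial_ci"),
    stringsAsFactors = FALSE
  )
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the model with each parameter in turn set to its lower and
#' upper bound, all others at base. Rows are sorted by decreasing ICUR span,
#' ties broken alphabetically by parameter name.
#'
#' @param params Base-case [static_params()] or [dynamic_params()].
#' @param ranges A data.frame with columns `parameter`, `low`, `high`
#'   (e.g. [static_ranges()]).
#' @return A data.frame of class `tornado` with columns `parameter`, `low`,
#'   `high`, `icur_at_low`, `icur_at_high`, `span`, plus attribute
#'   `base_icur`.
#' @export
one_way_dsa <- function(params, ranges) {
  stopifnot(is.data.frame(ranges),
            all(c("parameter", "low", "high") %in% names(ranges)))
  if (any(ranges$low > ranges$high)) {
    stop("every range must satisfy low <= high.", call. = FALSE)
  }
  base <- evaluate_cea(params)
  icur_at <- function(parameter, value) {
    evaluate_cea(set_param(params, parameter, value))$icur
  }
  out <- ranges[, c("parameter", "low", "high")]
  out$icur_at_low <- mapply(icur_at, ranges$parameter, ranges$low)
  out$icur_at_high <- mapply(icur_at, ranges$parameter, ranges$high)
  out$span <- abs(out$icur_at_high - out$icur_at_low)
  out <- out[order(-out$span, out$parameter), ]
  rownames(out) <- NULL
  attr(out, "base_icur") <- base$icur
  class(out) <- c("tornado", "data.frame")
  out
}

#' Scenario (multi-way) sensitivity analysis
#'
#' Re-evaluates the model under a named list of overrides. Plain names
#' replace parameter fields; in addition the switches `monitoring = FALSE`
#' (drop all monitoring visits), `ap_cost_multiplier` (scale the episode
#' cost), `life_years_only = TRUE` (all living-state utilities 1, AP
#' disutility 0, so effectiveness counts life-years only),
#' `horizon_weeks` (shorten the dynamic horizon; schedules are truncated)
#' and `mortality_source = "log_fit"` with `mortality_fit_points` (a
#' data.frame of `time_days`, `cumulative_mortality`; replaces the piecewise
#' schedule by the logarithmic-interpolation schedule) are understood.
#' Unknown keys raise an error.
#'
#' @param params Base-case [static_params()] or [dynamic_params()].
#' @param overrides Named list of overrides (empty list returns base case).
#' @return A `ce_comparison` for the scenario.
#' @export
scenario <- function(params, overrides = list()) {
  stopifnot(is.list(overrides))
  dynamic <- inherits(params, "dynamic_params")
  nms <- names(overrides)
  if (length(overrides) && (is.null(nms) || any(nms == ""))) {
    stop("all overrides must be named.", call. = FALSE)
  }
  if ("mortality_source" %in% nms &&
      identical(overrides$mortality_source, "log_fit") &&
      !"mortality_fit_points" %in% nms) {
    stop("`mortality_source = \"log_fit\"` requires `mortality_fit_points`.",
         call. = FALSE)
  }
  for (nm in nms) {
    v <- overrides[[nm]]
    if (nm == "monitoring") {
      if (!dynamic) stop("`monitoring` switch applies to the dynamic model only.",
                         call. = FALSE)
      if (!isTRUE(v)) params$monitoring_weeks <- integer(0)
    } else if (nm == "ap_cost_multiplier") {
      params$cost_ap_episode <- params$cost_ap_episode * v
    } else if (nm == "life_years_only") {
      if (isTRUE(v)) {
        unms <- if (dynamic) c("u_no_dysphagia", "u_dys_no_asp", "u_dys_asp")
                else c("u_aspiration", "u_no_aspiration")
        for (u in unms) params[[u]] <- 1
        params$du_ap <- 0
      }
    } else if (nm == "horizon_weeks") {
      if (!dynamic) stop("`horizon_weeks` applies to the dynamic model only.",
                         call. = FALSE)
      if (v > params$horizon_weeks) {
        stop("scenario horizon may not exceed the schedules' length (",
             params$horizon_weeks, " weeks).", call. = FALSE)
      }
      params$horizon_weeks <- as.integer(v)
      params$resolution <- params$resolution[seq_len(v)]
      params$mortality <- params$mortality[seq_len(v)]
      params$monitoring_weeks <-
        params$monitoring_weeks[params$monitoring_weeks <= v]
    } else if (nm == "mortality_source") {
      if (!dynamic) stop("`mortality_source` applies to the dynamic model only.",
                         call. = FALSE)
      if (identical(v, "log_fit")) {
        pts <- overrides$mortality_fit_points
        fit <- fit_log_survival(pts$time_days, pts$cumulative_mortality)
        params$mortality <- log_fit_mortality_schedule(fit,
                                                       params$horizon_weeks)
      } else if (!identical(v, "piecewise")) {
        stop("`mortality_source` must be \"piecewise\" or \"log_fit\".",
             call. = FALSE)
      }
    } else if (nm == "mortality_fit_points") {
      # consumed with mortality_source
    } else if (nm %in% names(params)) {
      params[[nm]] <- v
    } else {
      stop("unknown override key: `", nm, "`", call. = FALSE)
    }
  }
  evaluate_cea(revalidate(params))
}

# --- probabilistic sensitivity analysis ------------------------------------

#' Distribution descriptors for PSA parameters
#'
#' Helpers describing how one parameter is drawn per PSA iteration:
#' `dist_beta()` (method-of-moments from mean and SD), `dist_beta_counts()`
#' (`Beta(events, n - events)` from binomial source counts),
#' `dist_lognormal()` (from a ratio's point estimate and confidence
#' interval), `dist_gamma()` (method-of-moments) and `dist_fixed()`.
#'
#' @param mean,sd Moments on the natural scale.
#' @param events,n Binomial source counts.
#' @param point,low,high,conf_level Ratio point estimate and interval.
#' @param value Fixed value.
#' @return A list describing the distribution, class `psa_dist`.
#' @name psa_distributions
NULL

#' @rdname psa_distributions
#' @export
dist_beta <- function(mean, sd) {
  sh <- beta_from_moments(mean, sd)
  structure(list(dist = "beta", shape1 = sh[["shape1"]],
                 shape2 = sh[["shape2"]]), class = "psa_dist")
}

#' @rdname psa_distributions
#' @export
dist_beta_counts <- function(events, n) {
  stopifnot(events > 0, n > events)
  structure(list(dist = "beta", shape1 = events, shape2 = n - events),
            class = "psa_dist")
}

#' @rdname psa_distributions
#' @export
dist_lognormal <- function(point, low, high, conf_level = 0.95) {
  pars <- lognormal_from_ci(point, low, high, conf_level)
  structure(list(dist = "lognormal", meanlog = pars[["meanlog"]],
                 sdlog = pars[["sdlog"]]), class = "psa_dist")
}

#' @rdname psa_distributions
#' @export
dist_gamma <- function(mean, sd) {
  pars <- gamma_from_moments(mean, sd)
  structure(list(dist = "gamma", shape = pars[["shape"]],
                 rate = pars[["rate"]]), class = "psa_dist")
}

#' @rdname psa_distributions
#' @export
dist_fixed <- function(value) {
  structure(list(dist = "fixed", value = value), class = "psa_dist")
}

draw_dist <- function(d, n) {
  switch(d$dist,
         beta = stats::rbeta(n, d$shape1, d$shape2),
         lognormal = stats::rlnorm(n, d$meanlog, d$sdlog),
         gamma = stats::rgamma(n, d$shape, d$rate),
         fixed = rep(d$value, n),
         stop("unknown distribution: ", d$dist, call. = FALSE))
}

#' Default PSA specification for the static model
#'
#' Utilities are drawn beta with SDs back-calculated from their intervals
#' ([sd_from_interval()]); the two aspiration-pneumonia risks beta from
#' their binomial source counts; the episode cost gamma with SD equal to
#' `cost_sd_frac` of the mean. Thickener dosing and prices are held fixed.
#'
#' @param params Base-case [static_params()].
#' @param counts_aspirators,counts_non_aspirators Source counts `c(events, n)`.
#' @param cost_sd_frac SD of the AP cost as a fraction of its mean,
#'   default 0.20.
#' @return Named list of `psa_dist` objects keyed by parameter name.
#' @export
default_static_psa <- function(params,
                               counts_aspirators = c(10, 82),
                               counts_non_aspirators = c(1, 57),
                               cost_sd_frac = 0.20) {
  stopifnot(inherits(params, "static_params"))
  list(
    u_aspiration = dist_beta(params$u_aspiration,
                             sd_from_interval(0.135, 0.165)),
    u_no_aspiration = dist_beta(params$u_no_aspiration,
                                sd_from_interval(0.32, 0.42)),
    du_ap = dist_beta(params$du_ap, sd_from_interval(0.10, 0.15)),
    p_ap_aspirators = dist_beta_counts(counts_aspirators[1],
                                       counts_aspirators[2]),
    p_ap_non_aspirators = dist_beta_counts(counts_non_aspirators[1],
                                           counts_non_aspirators[2]),
    cost_ap_episode = dist_gamma(params$cost_ap_episode,
                                 cost_sd_frac * params$cost_ap_episode)
  )
}

#' Draw a matrix of PSA parameter values
#'
#' @param spec Named list of `psa_dist` descriptors.
#' @param n Number of iterations.
#' @param seed Integer seed; the draw is reproducible given `seed`.
#' @return A data.frame with `n` rows, one column per parameter.
#' @export
draw_psa_params <- function(spec, n, seed) {
  stopifnot(is.list(spec), length(spec) > 0, !is.null(names(spec)))
  if (n <= 0) stop("`n` must be positive.", call. = FALSE)
  set.seed(seed)
  as.data.frame(lapply(spec, draw_dist, n = n))
}

#' Probabilistic sensitivity analysis
#'
#' Draws all parameters independently from `spec` per iteration,
#' re-evaluates the model for each draw, and returns the incremental cost
#' and QALY per draw. Reproducible given `seed`.
#'
#' @param params Base-case [static_params()] or [dynamic_params()].
#' @param spec Named list of `psa_dist` objects; names must be parameter
#'   fields of `params` (see [default_static_psa()]).
#' @param n Number of iterations (> 0).
#' @param seed Integer seed.
#' @return A data.frame of class `psa_result` with columns `delta_cost`,
#'   `delta_qaly`, `icur`.
#' @export
psa <- function(params, spec, n = 10000, seed = 1) {
  if (n <= 0) stop("`n` must be positive.", call. = FALSE)
  unknown <- setdiff(names(spec), names(params))
  if (length(unknown)) {
    stop("PSA spec targets unknown parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  draws <- draw_psa_params(spec, n, seed)
  fast_static <- inherits(params, "static_params")
  base <- unclass(params)
  dc <- dq <- numeric(n)
  for (i in seq_len(n)) {
    p <- base
    for (nm in names(draws)) p[[nm]] <- draws[i, nm]
    if (fast_static) {
      vi <- static_arm_values(p, "intervention")
      vc <- static_arm_values(p, "comparator")
      dc[i] <- (vi$cost_dysphagia_treatment + vi$cost_ap_treatment) -
        (vc$cost_dysphagia_treatment + vc$cost_ap_treatment)
      dq[i] <- vi$qaly - vc$qaly
    } else {
      class(p) <- class(params)
      cmp <- evaluate_cea(p)
      dc[i] <- cmp$delta_cost
      dq[i] <- cmp$delta_qaly
    }
  }
  out <- data.frame(delta_cost = dc, delta_qaly = dq,
                    icur = ifelse(dq != 0, dc / dq, NA_real_))
  class(out) <- c("psa_result", "data.frame")
  out
}

#' Probability of cost-effectiveness at one threshold
#'
#' Fraction of PSA draws with non-negative net monetary benefit
#' `lambda * delta_qaly - delta_cost` at willingness-to-pay `lambda`.
#'
#' @param samples A [psa()] result (or any data.frame with `delta_cost`,
#'   `delta_qaly`).
#' @param threshold Willingness-to-pay per QALY.
#' @return Probability in `[0, 1]`.
#' @export
prob_cost_effective <- function(samples, threshold) {
  stopifnot(is.data.frame(samples), nrow(samples) > 0)
  mean(threshold * samples$delta_qaly - samples$delta_cost >= 0)
}

#' Cost-effectiveness acceptability curve
#'
#' @param samples A [psa()] result.
#' @param thresholds Vector of willingness-to-pay thresholds.
#' @return A data.frame of class `ceac` with columns `threshold`,
#'   `prob_cost_effective`.
#' @export
ceac <- function(samples, thresholds = seq(0, 300000, by = 1000)) {
  if (!is.data.frame(samples) || nrow(samples) == 0) {
    stop("`samples` must be a non-empty PSA result.", call. = FALSE)
  }
  out <- data.frame(
    threshold = thresholds,
    prob_cost_effective = vapply(thresholds, prob_cost_effective,
                                 numeric(1), samples = samples)
  )
  class(out) <- c("ceac", "data.frame")
  out
}

# --- plots ------------------------------------------------------------------

#' Tornado diagram of a one-way sensitivity analysis
#'
#' @param dsa A [one_way_dsa()] result.
#' @return A ggplot object: horizontal bars from the base-case ICUR to the
#'   ICUR at each parameter bound.
#' @export
plot_tornado <- function(dsa) {
  stopifnot(inherits(dsa, "tornado"))
  base <- attr(dsa, "base_icur")
  long <- rbind(
    data.frame(parameter = dsa$parameter, icur = dsa$icur_at_low,
               bound = "minimum"),
    data.frame(parameter = dsa$parameter, icur = dsa$icur_at_high,
               bound = "maximum")
  )
  long$parameter <- factor(long$parameter, levels = rev(dsa$parameter))
  ggplot2::ggplot(long, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = base, xend = .data$icur,
                                       colour = .data$bound),
                          linewidth = 4) +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(minimum = "grey60",
                                            maximum = "black")) +
    ggplot2::labs(x = "ICUR (currency per QALY)", y = NULL,
                  colour = "parameter at") +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param x A [ceac()] result.
#' @param threshold Optional vertical reference line (e.g. the national
#'   willingness-to-pay threshold).
#' @return A ggplot object.
#' @export
plot_ceac <- function(x, threshold = NULL) {
  stopifnot(inherits(x, "ceac"))
  p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$threshold,
                                       y = .data$prob_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (currency per QALY)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  }
  p
}
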