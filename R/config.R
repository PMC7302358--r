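# Configuration loading/validation and result reports. The canonical config
# is a YAML file with blocks `meta`, `static`, `dynamic`, `ranges`, `psa`;
# supplement-only values carry an `assumed_fields` provenance list.

config_field_error <- function(field, msg) {
  stop(sprintf("config field `%s`: %s", field, msg), call. = FALSE)
}

#' Load and validate a model configuration
#'
#' Reads a YAML configuration, validates every field against its domain and
#' the cross-field constraints (e.g. monitoring weeks within the horizon),
#' and builds the parameter objects. The `dynamic` block is optional: a
#' config with only a `static` block loads and supports static analyses.
#' Within the `dynamic` block, `u_no_dysphagia` and `prevalence_anchors`
#' have no main-source base value and must be supplied explicitly (the
#' shipped fixture provides flagged placeholders).
#'
#' @param path Path to the YAML file.
#' @return An object of class `model_config`: a list with `meta`, `static`
#'   ([static_params()]), `dynamic` ([dynamic_params()] or `NULL`),
#'   `static_counts`, `ranges`, `psa` (distribution list plus
#'   `n_iterations`) and `assumed_fields`.
#' @seealso [base_case_fixture()] for the shipped base-case configuration.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$static)) config_field_error("static", "block is required")

  s <- raw$static
  counts <- s$ap_counts
  if (!is.null(counts)) {
    for (grp in c("aspirators", "non_aspirators")) {
      g <- counts[[grp]]
      if (is.null(g$events) || is.null(g$n_patients) ||
          g$events < 0 || g$events > g$n_patients) {
        config_field_error(paste0("static.ap_counts.", grp),
                           "needs 0 <= events <= n_patients")
      }
    }
    p_asp <- counts$aspirators$events / counts$aspirators$n_patients
    p_non <- counts$non_aspirators$events / counts$non_aspirators$n_patients
  } else {
    p_asp <- s$p_ap_aspirators
    p_non <- s$p_ap_non_aspirators
    if (is.null(p_asp) || is.null(p_non)) {
      config_field_error("static.ap_counts",
                         "either ap_counts or explicit AP probabilities required")
    }
  }
  static <- tryCatch(
    static_params(
      dysphagia_weeks = s$dysphagia_weeks %||% 8,
      ap_weeks = s$ap_weeks %||% 2,
      p_ap_aspirators = p_asp,
      p_ap_non_aspirators = p_non,
      u_aspiration = s$u_aspiration,
      u_no_aspiration = s$u_no_aspiration,
      du_ap = s$du_ap,
      cost_ap_episode = s$cost_ap_episode,
      nutilis_daily_g = s$nutilis_daily_g,
      tin_g = s$tin_g,
      tin_price = s$tin_price),
    error = function(e) config_field_error("static", conditionMessage(e)))

  dynamic <- NULL
  if (!is.null(raw$dynamic)) {
    d <- raw$dynamic
    horizon <- d$horizon_weeks %||% 52
    if (is.null(d$u_no_dysphagia)) {
      config_field_error("dynamic.u_no_dysphagia",
                         paste("no main-source base value exists; supply a value",
                               "or use the shipped fixture's flagged placeholder"))
    }
    if (is.null(d$prevalence_anchors)) {
      config_field_error("dynamic.prevalence_anchors",
                         paste("no main-source base values exist; supply anchors",
                               "or use the shipped fixture's flagged placeholders"))
    }
    anchors <- do.call(rbind, lapply(d$prevalence_anchors, function(a) {
      data.frame(time_days = a$day, fraction_with_dysphagia = a$fraction)
    }))
    resolution <- tryCatch(
      calibrate_resolution(anchors, horizon_weeks = horizon),
      error = function(e) config_field_error("dynamic.prevalence_anchors",
                                             conditionMessage(e)))
    m <- d$mortality
    mortality <- mortality_schedule(m$p30_weekly, m$p90_weekly, m$rest_weekly,
                                    horizon_weeks = horizon)
    dynamic <- tryCatch(
      dynamic_params(
        baseline_ap_ir_weekly = d$baseline_ap_ir_weekly,
        rr_ap_no_asp = d$rr_ap_no_asp,
        rr_ap_asp = d$rr_ap_asp,
        rr_death_ap = d$rr_death_ap,
        deterioration_weekly = d$deterioration_weekly,
        resolution = resolution,
        mortality = mortality,
        u_no_dysphagia = d$u_no_dysphagia,
        u_dys_no_asp = d$u_dys_no_asp,
        u_dys_asp = d$u_dys_asp,
        du_ap = d$du_ap,
        cost_ap_episode = d$cost_ap_episode,
        cost_monitoring_visit = d$cost_monitoring_visit,
        monitoring_weeks = unlist(d$monitoring_weeks),
        nutilis_daily_g = d$nutilis_daily_g,
        tin_g = d$tin_g,
        tin_price = d$tin_price,
        horizon_weeks = horizon),
      error = function(e) config_field_error("dynamic", conditionMessage(e)))
  }

  counts_a <- if (!is.null(counts)) {
    c(counts$aspirators$events, counts$aspirators$n_patients)
  } else c(NA, NA)
  counts_n <- if (!is.null(counts)) {
    c(counts$non_aspirators$events, counts$non_aspirators$n_patients)
  } else c(NA, NA)

  ranges <- if (!is.null(counts)) {
    static_ranges(counts_a, counts_n)
  } else NULL

  psa_block <- raw$psa %||% list()
  psa_spec <- if (!is.null(counts)) {
    default_static_psa(static, counts_a, counts_n,
                       cost_sd_frac = psa_block$ap_cost_sd_frac %||% 0.20)
  } else NULL

  structure(list(
    meta = list(currency = raw$meta$currency %||% "PLN",
                threshold = raw$meta$threshold_per_qaly %||% 147024),
    static = static,
    dynamic = dynamic,
    static_counts = list(aspirators = counts_a, non_aspirators = counts_n),
    ranges = ranges,
    psa = c(psa_spec, list(n_iterations = psa_block$n_iterations %||% 10000)),
    assumed_fields = unlist(raw$assumed_fields) %||% character(0)
  ), class = "model_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_config <- function(x, ...) {
  cat("model_config:", x$meta$currency,
      sprintf("(threshold %s/QALY)\n", format(x$meta$threshold, big.mark = ",")))
  cat("  static block: present\n")
  cat("  dynamic block:", if (is.null(x$dynamic)) "absent" else
    sprintf("present (%d-week horizon)", x$dynamic$horizon_weeks), "\n")
  if (length(x$assumed_fields)) {
    cat("  assumed (non-source) fields:",
        paste(x$assumed_fields, collapse = ", "), "\n")
  }
  invisible(x)
}

comparison_report_table <- function(comparison) {
  i <- comparison$intervention
  c_ <- comparison$comparator
  data.frame(
    category = c("effects_qaly", "total_costs", "cost_dysphagia_treatment",
                 "cost_ap_treatment", "cost_monitoring", "icur"),
    intervention = c(i$qaly, i$cost_total, i$cost_dysphagia_treatment,
                     i$cost_ap_treatment, i$cost_monitoring, NA),
    comparator = c(c_$qaly, c_$cost_total, c_$cost_dysphagia_treatment,
                   c_$cost_ap_treatment, c_$cost_monitoring, NA),
    incremental = c(comparison$delta_qaly, comparison$delta_cost,
                    i$cost_dysphagia_treatment - c_$cost_dysphagia_treatment,
                    i$cost_ap_treatment - c_$cost_ap_treatment,
                    i$cost_monitoring - c_$cost_monitoring,
                    comparison$icur),
    stringsAsFactors = FALSE
  )
}

#' Write a cost-utility comparison report
#'
#' Serialises a comparison as a table of per-arm effects, total and
#' component costs, and the ICUR, at full numeric precision (display
#' rounding is left to the reader; the `print()` method rounds). CSV and
#' JSON reports carry numerically identical payloads.
#'
#' @param comparison A `ce_comparison`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return The report data.frame, invisibly.
#' @export
write_report <- function(comparison, path, format = c("csv", "json")) {
  stopifnot(inherits(comparison, "ce_comparison"))
  format <- match.arg(format)
  tab <- comparison_report_table(comparison)
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(model = comparison$model, dominance = comparison$dominance,
           report = tab),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(tab)
}

#' Read back a comparison report
#'
#' @param path Path to a report written by [write_report()].
#' @param format `"csv"` or `"json"`.
#' @return The report data.frame.
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    x$report
  }
}

#' Export derived model parameters as a JSON block
#'
#' Serialises a named list of derived parameters (e.g. a pooled incidence
#' rate, relative risks, a calibrated resolution schedule) so it can be
#' merged back into a model configuration.
#'
#' @param params Named list of numeric values or vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_derived_parameters <- function(params, path) {
  stopifnot(is.list(params), !is.null(names(params)))
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
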