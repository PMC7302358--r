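Package: dysphagiaCE
Title: Cost-Utility Models for Thickened Fluids in Post-Stroke Dysphagia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-utility models for xanthan gum-based
    food-consistency modification versus routine clinical practice in adult
    post-stroke dysphagia, from the public-payer perspective. Provides a
    closed-form static model with a fixed 8-week dysphagia horizon and a
    weekly-cycle Markov cohort model over one year with dysphagia resolution,
    deterioration, aspiration-pneumonia tunnel states, and mortality. Includes
    the parameter-estimation toolkit (cumulative-risk to incidence-rate
    conversion, pooled rates, relative risks with log-normal intervals,
    distribution back-calculation from intervals, prevalence-anchored
    calibration of resolution schedules), deterministic one-way and scenario
    sensitivity analyses, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and seed-reproducible synthetic
    data generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
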