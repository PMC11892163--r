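Package: svymediate
Title: Survey-Weighted Counterfactual Mediation Analysis on the Odds-Ratio Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Regression-based counterfactual mediation analysis for complex
    survey data with binary exposures, mediators and outcomes. Combines
    survey-weighted logistic models for the mediator and the outcome into
    natural direct, natural indirect and total effect odds ratios, the
    log-scale proportion mediated, and percentile bootstrap confidence
    intervals that resample primary sampling units within strata. Includes a
    synthetic stratified-cluster cohort generator with an exact counterfactual
    oracle for method validation, design-based prevalence estimation, and a
    config-driven pipeline that runs full bidirectional analysis grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
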