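#' Declare one mediation analysis cell
#'
#' Specifies a single counterfactual mediation contrast: binary exposure
#' (contrast `a = 1` vs `a* = 0`), binary mediator, binary outcome,
#' adjustment covariates, whether the outcome model carries an
#' exposure-by-mediator interaction, and the covariate setting at which the
#' conditional odds ratios are evaluated.
#'
#' The mediator and outcome must be distinct, and the exposure is assumed to
#' precede both (here: exposure more than 12 months ago, mediator and
#' outcome within the last 12 months). Because the mediator and outcome
#' share a recall window, the machinery is run in both causal orderings
#' (recursive models); swapping `mediator` and `outcome` gives the reverse
#' direction.
#'
#' @param exposure,mediator,outcome Column names of 0/1 variables.
#' @param covariates Character vector of adjustment columns (default age
#'   group and education).
#' @param interaction Include the exposure-by-mediator product term in the
#'   outcome model (default `TRUE`; the general formulas reduce to the
#'   no-interaction product method when the term is absent).
#' @param covariate_evaluation `"weighted_mean"` (default: weighted mean of
#'   the indicator-coded covariate columns in the analysis sample),
#'   `"modal"` (most frequent weighted covariate cell), or `"explicit"`
#'   with `c_setting`.
#' @param c_setting Named numeric vector over indicator-coded covariate
#'   design columns when `covariate_evaluation = "explicit"`.
#' @return A `mediation_spec`.
#' @examples
#' mediation_spec("sae_lifetime", "heavy_tobacco", "depression")
#' @export
mediation_spec <- function(exposure, mediator, outcome,
                           covariates = c("age_group", "education"),
                           interaction = TRUE,
                           covariate_evaluation = c("weighted_mean", "modal",
                                                    "explicit"),
                           c_setting = NULL) {
  covariate_evaluation <- arg_match(covariate_evaluation)
  if (identical(mediator, outcome)) {
    abort("`mediator` and `outcome` must be distinct columns")
  }
  if (exposure %in% c(mediator, outcome)) {
    abort("`exposure` must be distinct from mediator and outcome")
  }
  if (covariate_evaluation == "explicit" &&
      (is.null(c_setting) ||
       (length(c_setting) > 0 && is.null(names(c_setting))))) {
    abort("explicit evaluation requires a named `c_setting`")
  }
  structure(
    list(exposure = exposure, mediator = mediator, outcome = outcome,
         covariates = covariates, interaction = interaction,
         covariate_evaluation = covariate_evaluation, c_setting = c_setting),
    class = "mediation_spec"
  )
}

#' @export
print.mediation_spec <- function(x, ...) {
  cat("<mediation_spec>", x$exposure, "->", x$mediator, "->", x$outcome, "\n")
  cat("  covariates:", paste(x$covariates, collapse = ", "),
      " interaction:", x$interaction,
      " evaluation:", x$covariate_evaluation, "\n")
  invisible(x)
}

#' Covariate evaluation point for conditional odds ratios
#'
#' Computes the setting of the indicator-coded covariate columns at which
#' [combine_effects()] conditions: the weighted mean of each indicator
#' column (default), the modal (most frequent, by weight) covariate cell as
#' a 0/1 indicator vector, or an explicit user-supplied setting passed
#' through unchanged.
#'
#' @param data Analysis records (already listwise-deleted).
#' @param covariates Covariate column names.
#' @param weights Numeric weight vector (or `NULL` for unit weights).
#' @param method `"weighted_mean"`, `"modal"`, or `"explicit"`.
#' @param c_setting Named vector for `"explicit"`.
#' @return Named numeric vector over the non-intercept covariate design
#'   columns.
#' @export
covariate_setting <- function(data, covariates, weights = NULL,
                              method = c("weighted_mean", "modal", "explicit"),
                              c_setting = NULL) {
  method <- arg_match(method)
  if (method == "explicit") return(c_setting)
  if (!length(covariates)) return(numeric(0))
  X <- model.matrix(stats::reformulate(covariates), data = data)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (is.null(weights)) weights <- rep(1, nrow(X))
  if (method == "weighted_mean") {
    return(colSums(X * weights) / sum(weights))
  }
  # modal: most frequent weighted cell of the joint covariate distribution
  key <- do.call(paste, c(as.data.frame(X), sep = "\r"))
  tot <- tapply(weights, key, sum)
  best <- names(tot)[which.max(tot)]
  row <- X[match(best, key), ]
  setNames(as.numeric(row), colnames(X))
}

#' Combine mediator and outcome fits into natural-effect odds ratios
#'
#' The central regression-based counterfactual computation. With outcome
#' model \eqn{\mathrm{logit} P(Y=1|a,m,c) = \theta_0 + \theta_1 a +
#' \theta_2 m + \theta_3 am + \theta_4'c} and mediator model
#' \eqn{\mathrm{logit} P(M=1|a,c) = \beta_0 + \beta_1 a + \beta_2'c}, the
#' conditional natural direct and indirect effect odds ratios for contrast
#' `a = 1` vs `a* = 0` at covariate setting `c` (valid when the outcome is
#' rare) are
#' \deqn{OR^{NDE} = e^{\theta_1}\frac{1 + e^{\theta_2 + \theta_3 + \beta_0 +
#'   \beta_2'c}}{1 + e^{\theta_2 + \beta_0 + \beta_2'c}}}
#' \deqn{OR^{NIE} = \frac{(1 + e^{\beta_0 + \beta_2'c})
#'   (1 + e^{\beta_0 + \beta_1 + \beta_2'c + \theta_2 + \theta_3})}
#'   {(1 + e^{\beta_0 + \beta_1 + \beta_2'c})
#'   (1 + e^{\beta_0 + \beta_2'c + \theta_2 + \theta_3})}}
#' and \eqn{OR^{TE} = OR^{NDE} \times OR^{NIE}} (the decomposition holds
#' exactly by construction). Without the interaction term \eqn{\theta_3 = 0}
#' throughout.
#'
#' @param outcome_fit,mediator_fit `logistic_fit` objects for the outcome
#'   and mediator models (same exposure and covariate coding).
#' @param spec A [mediation_spec()].
#' @param c_setting Named numeric vector over covariate design columns (see
#'   [covariate_setting()]).
#' @return Named numeric vector `c(or_nde, or_nie, or_te)`.
#' @examples
#' beta <- c("(Intercept)" = -2, a = 0.6)
#' theta <- c("(Intercept)" = -6, a = 1, m = 0.7, "a:m" = 0.2)
#' spec <- mediation_spec("a", "m", "y", covariates = character())
#' combine_effects(logistic_fit(theta), logistic_fit(beta), spec,
#'                 c_setting = numeric())
#' @export
combine_effects <- function(outcome_fit, mediator_fit, spec, c_setting) {
  stopifnot(inherits(outcome_fit, "logistic_fit"),
            inherits(mediator_fit, "logistic_fit"),
            inherits(spec, "mediation_spec"))
  bm <- coef(mediator_fit)
  th <- coef(outcome_fit)
  if (anyNA(bm) || anyNA(th) || any(!is.finite(c(bm, th)))) {
    abort("non-finite coefficient in mediator or outcome fit")
  }
  need <- function(cf, nm, what) {
    if (!nm %in% names(cf)) abort(paste0(what, " coefficient `", nm, "` not found"))
    cf[[nm]]
  }
  b1 <- need(bm, spec$exposure, "mediator-model exposure")
  th1 <- need(th, spec$exposure, "outcome-model exposure")
  th2 <- need(th, spec$mediator, "outcome-model mediator")
  th3 <- if (spec$interaction) {
    inm <- paste(spec$exposure, spec$mediator, sep = ":")
    inm2 <- paste(spec$mediator, spec$exposure, sep = ":")
    if (inm %in% names(th)) th[[inm]]
    else need(th, inm2, "outcome-model interaction")
  } else 0

  cs <- c_setting
  if (length(cs)) {
    missing_cs <- setdiff(names(cs), names(bm))
    if (length(missing_cs)) {
      abort(paste0("covariate columns absent from mediator fit: ",
                   paste(missing_cs, collapse = ", ")))
    }
  }
  b_lp0 <- bm[["(Intercept)"]] +
    if (length(cs)) sum(bm[names(cs)] * as.numeric(cs)) else 0

  or_formulas(th1, th2, th3, b_lp0, b1)
}

#' Proportion mediated on the log odds-ratio scale
#'
#' The ratio of the natural indirect effect to the total effect on the log
#' scale, \eqn{PM = \log(OR^{NIE}) / \log(OR^{TE})}: the fraction of the
#' total effect attributable to the mediated pathway.
#'
#' A null total effect (`or_te == 1`) makes the ratio undefined; `NA` is
#' returned with a warning rather than a silent zero. When the direct and
#' indirect effects point in opposite directions the value falls outside
#' `[0, 1]` and is returned as-is with a warning.
#'
#' @param or_nie,or_te Positive odds ratios.
#' @return The proportion mediated (unitless; multiply by 100 for percent).
#' @examples
#' proportion_mediated(1.23, 4.09)  # 0.147
#' @export
proportion_mediated <- function(or_nie, or_te) {
  if (any(c(or_nie, or_te) <= 0)) abort("odds ratios must be positive")
  if (or_te == 1) {
    warn("proportion mediated undefined: total effect is exactly null")
    return(NA_real_)
  }
  pm <- log(or_nie) / log(or_te)
  if (is.finite(pm) && (pm < 0 || pm > 1)) {
    warn("direct and indirect effects point in opposite directions; proportion mediated outside [0, 1]")
  }
  pm
}

#' Run one mediation analysis cell (point estimates)
#'
#' Fits the survey-weighted mediator model (mediator on exposure and
#' covariates) and outcome model (outcome on exposure, mediator, their
#' optional interaction, and covariates) on the listwise-complete records,
#' evaluates [combine_effects()] at the configured covariate setting, and
#' computes the proportion mediated. Confidence intervals are filled by
#' [bootstrap_mediation()].
#'
#' @param data Individual records for one sex stratum (the analysis is run
#'   sex-specifically; `data` should already be filtered).
#' @param spec A [mediation_spec()].
#' @param design A [survey_design()].
#' @return A `mediation_estimate`: effects table (`or_te`, `or_nde`,
#'   `or_nie` with empty CI columns), `pm`, `n_used`, outcome and mediator
#'   prevalence metadata, and the fitted models.
#' @examples
#' ch <- generate_cohort(cohort_params("female"), 2000, seed = 1)
#' run_mediation(ch, mediation_spec("sae_lifetime", "heavy_tobacco",
#'                                  "depression"))
#' @export
run_mediation <- function(data, spec, design = survey_design()) {
  stopifnot(inherits(spec, "mediation_spec"))
  vars <- c(spec$exposure, spec$mediator, spec$outcome, spec$covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    abort(paste0("columns not found: ", paste(missing_cols, collapse = ", ")))
  }
  cc <- stats::complete.cases(data[vars])
  data <- data[cc, , drop = FALSE]
  if (length(unique(data[[spec$exposure]])) < 2) {
    abort("an exposure class is empty after listwise deletion")
  }

  wcol <- design$weight
  if (!is.null(wcol) && !wcol %in% names(data)) wcol <- NULL
  w <- if (is.null(wcol)) rep(1, nrow(data)) else data[[wcol]]

  mediator_fit <- fit_weighted_logistic(
    data, spec$mediator, c(spec$exposure, spec$covariates), weights = wcol)
  outcome_fit <- fit_weighted_logistic(
    data, spec$outcome, c(spec$exposure, spec$mediator, spec$covariates),
    weights = wcol,
    interaction = if (spec$interaction) c(spec$exposure, spec$mediator))

  if (outcome_fit$separation_detected || mediator_fit$separation_detected) {
    abort("separation detected in a point-estimate fit; effects are not identified")
  }

  cs <- covariate_setting(data, spec$covariates, w,
                          method = spec$covariate_evaluation,
                          c_setting = spec$c_setting)
  ors <- combine_effects(outcome_fit, mediator_fit, spec, cs)
  pm <- withCallingHandlers(
    proportion_mediated(ors[["or_nie"]], ors[["or_te"]]),
    warning = function(w) invokeRestart("muffleWarning"))

  new_mediation_estimate(
    ors = ors, pm = pm, spec = spec, n_used = nrow(data),
    c_setting = cs,
    outcome_prevalence = sum(w * data[[spec$outcome]]) / sum(w),
    mediator_prevalence = sum(w * data[[spec$mediator]]) / sum(w),
    outcome_fit = outcome_fit, mediator_fit = mediator_fit
  )
}

new_mediation_estimate <- function(ors, pm, spec, n_used, c_setting,
                                   outcome_prevalence, mediator_prevalence,
                                   outcome_fit = NULL, mediator_fit = NULL,
                                   ci = NULL, pm_ci = NULL,
                                   n_bootstrap_ok = NA_integer_,
                                   bootstrap = NULL) {
  effects <- tibble(
    effect = c("total", "natural_direct", "natural_indirect"),
    or = unname(ors[c("or_te", "or_nde", "or_nie")]),
    ci_low = NA_real_, ci_high = NA_real_
  )
  if (!is.null(ci)) {
    effects$ci_low <- ci[, 1]
    effects$ci_high <- ci[, 2]
  }
  structure(
    list(effects = effects, pm = pm, pm_ci = pm_ci,
         pm_undefined = is.na(pm),
         n_used = n_used, n_bootstrap_ok = n_bootstrap_ok,
         spec = spec, c_setting = c_setting,
         outcome_prevalence = outcome_prevalence,
         mediator_prevalence = mediator_prevalence,
         outcome_fit = outcome_fit, mediator_fit = mediator_fit,
         bootstrap = bootstrap),
    class = "mediation_estimate"
  )
}

#' @export
print.mediation_estimate <- function(x, ...) {
  cat("<mediation_estimate>", x$spec$exposure, "->", x$spec$mediator, "->",
      x$spec$outcome, "\n")
  cat("  n =", x$n_used,
      " outcome prevalence =", sprintf("%.1f%%", 100 * x$outcome_prevalence), "\n")
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    ci_txt <- if (is.na(eff$ci_low[i])) "" else
      sprintf(" (95%% BCI %.2f, %.2f)", eff$ci_low[i], eff$ci_high[i])
    cat(sprintf("  %-17s OR = %.2f%s\n", eff$effect[i], eff$or[i], ci_txt))
  }
  if (x$pm_undefined) {
    cat("  PM: undefined (null total effect)\n")
  } else {
    cat(sprintf("  PM = %.1f%%\n", 100 * x$pm))
  }
  if (!is.na(x$n_bootstrap_ok)) {
    cat("  bootstrap replicates used:", x$n_bootstrap_ok, "\n")
  }
  invisible(x)
}
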