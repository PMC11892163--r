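#' Structural parameters for the synthetic survey cohort generator
#'
#' A `cohort_params` object holds everything needed to simulate a
#' stratified-cluster survey cohort with a known causal structure:
#' categorical covariate distributions (six age groups, three education
#' levels), a logistic exposure model, a logistic mediator model, a logistic
#' outcome model with an optional exposure-by-mediator interaction, auxiliary
#' logistic models for additional health variables, and the survey-design
#' settings (strata, primary sampling units, weight dispersion).
#'
#' All structural coefficients are on the logit scale. Categorical covariates
#' are indicator-coded against their first level (age 18-25, education high).
#'
#' @param sex `"female"` or `"male"`. Selects the default calibration: model
#'   intercepts are solved numerically so that the implied marginal
#'   prevalences of the exposure and the four health variables match the
#'   sex-specific targets of a large German general-population survey
#'   (lifetime sexual-assault experience 14.0% / 2.7%, hazardous alcohol use
#'   0.7% / 0.9%, heavy tobacco use 7.8% / 12.3%, frequent cannabis use
#'   1.0% / 2.6%, depression 10.7% / 5.6% for women / men).
#' @param ... Named components overriding the defaults, e.g.
#'   `mediator_model = list(...)` or `design = list(n_strata = 5)`. Overridden
#'   intercepts are kept as given (no recalibration).
#'
#' @return An object of class `cohort_params`: a named list with components
#'   `sex`, `age_probs`, `edu_probs`, `exposure_model`, `mediator_model`
#'   (fields `intercept`, `exposure`, `covariates`), `outcome_model` (fields
#'   `intercept`, `exposure`, `mediator`, `interaction`, `covariates`),
#'   `aux_models`, `mediator_name`, `outcome_name`, `childhood_given_exposure`,
#'   `repeated_given_exposure`, `recent_rate`, `design`
#'   (`n_strata`, `psus_per_stratum`, `weight_sdlog`), and `missing_rates`.
#'
#' @examples
#' p <- cohort_params("female")
#' p$outcome_model$exposure   # structural log-OR of exposure on depression
#' @export
cohort_params <- function(sex = c("female", "male"), ...) {
  sex <- arg_match(sex)
  tg <- prevalence_targets(sex)

  base <- list(
    sex = sex,
    age_probs = tg$age_probs,
    edu_probs = tg$edu_probs,
    exposure_model = list(
      intercept = NA_real_,
      covariates = c(age = 0.2, age = 0.3, age = 0.3, age = 0.2, age = 0.1,
                     edu = 0.1, edu = 0.2)
    ),
    mediator_model = list(
      intercept = NA_real_,
      exposure = 0.6,
      covariates = c(age = 0.1, age = 0.0, age = -0.1, age = -0.3, age = -0.7,
                     edu = 0.5, edu = 0.8)
    ),
    outcome_model = list(
      intercept = NA_real_,
      exposure = 1.1,
      mediator = 0.65,
      interaction = 0.15,
      covariates = c(age = 0.0, age = -0.1, age = -0.1, age = -0.2, age = -0.3,
                     edu = 0.2, edu = 0.4)
    ),
    aux_models = list(
      hazardous_alcohol = list(
        intercept = NA_real_, exposure = 0.9,
        covariates = c(age = -0.2, age = -0.4, age = -0.6, age = -0.9, age = -1.2,
                       edu = 0.2, edu = 0.4)
      ),
      frequent_cannabis = list(
        intercept = NA_real_, exposure = 1.1,
        covariates = c(age = -0.3, age = -0.8, age = -1.3, age = -1.8, age = -2.5,
                       edu = 0.3, edu = 0.6)
      )
    ),
    mediator_name = "heavy_tobacco",
    outcome_name = "depression",
    childhood_given_exposure = tg$childhood / tg$exposure,
    repeated_given_exposure = 0.4,
    recent_rate = 0.005,
    design = list(n_strata = 10, psus_per_stratum = 20, weight_sdlog = 0.5),
    missing_rates = c(hazardous_alcohol = 0.045, heavy_tobacco = 0.003,
                      frequent_cannabis = 0.002, depression = 0)
  )
  params <- modifyList(base, list(...))
  params <- calibrate_params(params, tg)
  validate_params(params)
  structure(params, class = "cohort_params")
}

# Sex-specific marginal targets and covariate distributions (weighted
# column percentages of the survey the generator emulates, renormalized).
prevalence_targets <- function(sex) {
  if (sex == "female") {
    list(
      age_probs = c(11.5, 17.1, 16.4, 21.3, 19.2, 14.3) / 99.8,
      edu_probs = c(36.5, 35.2, 28.1) / 99.8,
      exposure = 0.140, childhood = 0.031,
      hazardous_alcohol = 0.007, heavy_tobacco = 0.078,
      frequent_cannabis = 0.010, depression = 0.107
    )
  } else {
    list(
      age_probs = c(12.5, 18.0, 16.2, 21.8, 18.7, 12.6) / 99.8,
      edu_probs = c(36.6, 28.9, 34.4) / 99.9,
      exposure = 0.027, childhood = 0.008,
      hazardous_alcohol = 0.009, heavy_tobacco = 0.123,
      frequent_cannabis = 0.026, depression = 0.056
    )
  }
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("<cohort_params> sex:", x$sex, "\n")
  cat("  mediator:", x$mediator_name, " outcome:", x$outcome_name, "\n")
  cat("  exposure logit intercept:", format(x$exposure_model$intercept, digits = 4), "\n")
  cat("  mediator model: b0 =", format(x$mediator_model$intercept, digits = 4),
      " b1 =", x$mediator_model$exposure, "\n")
  cat("  outcome model: th0 =", format(x$outcome_model$intercept, digits = 4),
      " th1 =", x$outcome_model$exposure, " th2 =", x$outcome_model$mediator,
      " th3 =", x$outcome_model$interaction, "\n")
  cat("  design:", x$design$n_strata, "strata x", x$design$psus_per_stratum,
      "PSUs, weight sdlog", x$design$weight_sdlog, "\n")
  invisible(x)
}

# Enumerate the finite covariate support: 18 (age x education) cells with
# joint probabilities and the indicator-coded covariate linear predictor
# under a coefficient vector laid out as (5 age, 2 education).
covariate_support <- function(params) {
  grid <- expand.grid(age = seq_len(6), edu = seq_len(3))
  grid$prob <- params$age_probs[grid$age] * params$edu_probs[grid$edu]
  grid
}

support_lp <- function(grid, covariates) {
  age_c <- c(0, covariates[seq_len(5)])
  edu_c <- c(0, covariates[6:7])
  age_c[grid$age] + edu_c[grid$edu]
}

# Solve a model intercept so the implied marginal prevalence over the
# enumerated support equals the target exactly.
solve_intercept <- function(target, lp, prob) {
  f <- function(b0) sum(prob * plogis(b0 + lp)) - target
  uniroot(f, c(-25, 10), tol = 1e-12)$root
}

calibrate_params <- function(params, tg) {
  grid <- covariate_support(params)

  # exposure: marginal over covariate cells
  if (is.na(params$exposure_model$intercept)) {
    lp_a <- support_lp(grid, params$exposure_model$covariates)
    params$exposure_model$intercept <- solve_intercept(tg$exposure, lp_a, grid$prob)
  }
  lp_a <- support_lp(grid, params$exposure_model$covariates)
  p_a <- plogis(params$exposure_model$intercept + lp_a)

  # mediator: marginal over cells x exposure
  mm <- params$mediator_model
  if (is.na(mm$intercept)) {
    lp_m <- support_lp(grid, mm$covariates)
    lp2 <- c(lp_m, lp_m + mm$exposure)
    pr2 <- c(grid$prob * (1 - p_a), grid$prob * p_a)
    params$mediator_model$intercept <-
      solve_intercept(tg[[params$mediator_name]], lp2, pr2)
  }

  # outcome: marginal over cells x exposure x mediator
  om <- params$outcome_model
  if (is.na(om$intercept)) {
    lp_m <- params$mediator_model$intercept + support_lp(grid, params$mediator_model$covariates)
    lp_y <- support_lp(grid, om$covariates)
    p_m0 <- plogis(lp_m)                                   # mediator prob, a = 0
    p_m1 <- plogis(lp_m + params$mediator_model$exposure)  # a = 1
    lp4 <- c(lp_y,                                   # a=0, m=0
             lp_y + om$mediator,                     # a=0, m=1
             lp_y + om$exposure,                     # a=1, m=0
             lp_y + om$exposure + om$mediator + om$interaction)  # a=1, m=1
    pr4 <- c(grid$prob * (1 - p_a) * (1 - p_m0),
             grid$prob * (1 - p_a) * p_m0,
             grid$prob * p_a * (1 - p_m1),
             grid$prob * p_a * p_m1)
    params$outcome_model$intercept <-
      solve_intercept(tg[[params$outcome_name]], lp4, pr4)
  }

  # auxiliary health variables: marginal over cells x exposure
  for (nm in names(params$aux_models)) {
    am <- params$aux_models[[nm]]
    if (is.na(am$intercept)) {
      lp_x <- support_lp(grid, am$covariates)
      lp2 <- c(lp_x, lp_x + am$exposure)
      pr2 <- c(grid$prob * (1 - p_a), grid$prob * p_a)
      params$aux_models[[nm]]$intercept <- solve_intercept(tg[[nm]], lp2, pr2)
    }
  }
  params
}

validate_params <- function(params) {
  stopifnot(
    abs(sum(params$age_probs) - 1) < 1e-8,
    abs(sum(params$edu_probs) - 1) < 1e-8,
    length(params$mediator_model$covariates) == 7,
    length(params$outcome_model$covariates) == 7,
    params$design$n_strata >= 1,
    params$design$psus_per_stratum >= 1,
    params$design$weight_sdlog >= 0,
    all(params$missing_rates >= 0), all(params$missing_rates <= 1)
  )
  if (any(params$missing_rates > 0.05)) {
    warn("missing_rates above 0.05 exceed the default missingness regime")
  }
  invisible(params)
}
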