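# Shared parameter sets and small oracles used across test files.

# Parameter set for estimator-recovery checks: common exposure (~33%) and a
# moderately rare outcome (~5.5%) so sampling error at n = 2e5 and the
# rare-outcome approximation are both small relative to the 0.05 log-OR
# tolerance.
recovery_params <- function() {
  cohort_params(
    "female",
    exposure_model = list(intercept = -1.0),
    mediator_model = list(intercept = -2.0, exposure = 0.7),
    outcome_model = list(intercept = -3.6, exposure = 1.0, mediator = 0.7,
                         interaction = 0.2)
  )
}

# Null-mediation parameters: exposure does not move the mediator.
null_mediation_params <- function() {
  cohort_params("female", mediator_model = list(exposure = 0))
}

# Natural-effect ORs of the regression formulas evaluated at the TRUE
# structural coefficients (the estimator's probability limit), at a given
# covariate indicator setting. Independent of the fitting code path.
formula_truth <- function(params, c_setting) {
  mm <- params$mediator_model
  om <- params$outcome_model
  b_lp0 <- mm$intercept + sum(mm$covariates * c_setting)
  e <- function(x) exp(x)
  th2 <- om$mediator; th3 <- om$interaction; b1 <- mm$exposure
  or_nde <- e(om$exposure) * (1 + e(th2 + th3 + b_lp0)) / (1 + e(th2 + b_lp0))
  or_nie <- ((1 + e(b_lp0)) * (1 + e(b_lp0 + b1 + th2 + th3))) /
    ((1 + e(b_lp0 + b1)) * (1 + e(b_lp0 + th2 + th3)))
  c(or_te = or_nde * or_nie, or_nde = or_nde, or_nie = or_nie)
}

# Population mean of the non-reference covariate indicators.
population_c <- function(params) c(params$age_probs[-1], params$edu_probs[-1])

# Brute-force Monte-Carlo counterfactual oracle: simulates mediator and
# outcome potential values from the structural equations at a fixed
# covariate cell and returns the three ORs plus binomial standard errors
# of the underlying risks.
mc_counterfactual <- function(params, c_setting, n_draws, seed) {
  mm <- params$mediator_model
  om <- params$outcome_model
  b_lp0 <- mm$intercept + sum(mm$covariates * c_setting)
  y_lp0 <- om$intercept + sum(om$covariates * c_setting)
  withr::with_seed(seed, {
    m0 <- rbinom(n_draws, 1, plogis(b_lp0))               # M under a* = 0
    m1 <- rbinom(n_draws, 1, plogis(b_lp0 + mm$exposure)) # M under a = 1
    y_draw <- function(a, m) {
      rbinom(n_draws, 1, plogis(y_lp0 + om$exposure * a + om$mediator * m +
                                  om$interaction * a * m))
    }
    r00 <- mean(y_draw(0, m0))
    r10 <- mean(y_draw(1, m0))
    r11 <- mean(y_draw(1, m1))
  })
  odds <- function(p) p / (1 - p)
  list(
    or_nde = odds(r10) / odds(r00),
    or_nie = odds(r11) / odds(r10),
    or_te = odds(r11) / odds(r00),
    risks = c(r00 = r00, r10 = r10, r11 = r11),
    se = sqrt(c(r00, r10, r11) * (1 - c(r00, r10, r11)) / n_draws)
  )
}
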