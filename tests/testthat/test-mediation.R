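spec_noc <- function(interaction = TRUE) {
  mediation_spec("a", "m", "y", covariates = character(),
                 interaction = interaction,
                 covariate_evaluation = "explicit", c_setting = numeric())
}

test_that("combine_effects collapses correctly when a pathway is absent", {
  beta0 <- c("(Intercept)" = -2, a = 0)
  theta <- c("(Intercept)" = -5, a = 0.9, m = 0.7, "a:m" = 0.2)
  ors <- combine_effects(logistic_fit(theta), logistic_fit(beta0),
                         spec_noc(), c_setting = numeric())
  expect_identical(unname(ors["or_nie"]), 1)

  beta <- c("(Intercept)" = -2, a = 0.6)
  theta0 <- c("(Intercept)" = -5, a = 0.9, m = 0, "a:m" = 0)
  ors2 <- combine_effects(logistic_fit(theta0), logistic_fit(beta),
                          spec_noc(), c_setting = numeric())
  expect_identical(unname(ors2["or_nie"]), 1)
  expect_equal(unname(ors2["or_nde"]), exp(0.9), tolerance = 1e-14)

  # interaction flag off ignores the interaction coefficient
  theta_i <- c("(Intercept)" = -5, a = 0.9, m = 0.7, "a:m" = 0.4)
  no_int <- combine_effects(logistic_fit(theta_i), logistic_fit(beta),
                            spec_noc(interaction = FALSE), numeric())
  with_int0 <- combine_effects(
    logistic_fit(c("(Intercept)" = -5, a = 0.9, m = 0.7, "a:m" = 0)),
    logistic_fit(beta), spec_noc(), numeric())
  expect_equal(no_int, with_int0, tolerance = 1e-14)
})

test_that("combine_effects matches the exact oracle for a rare outcome", {
  p <- cohort_params("female", outcome_model = list(intercept = -6))
  tr <- true_effects(p, "weighted_mean")
  f <- formula_truth(p, tr$c_setting)
  for (nm in c("or_te", "or_nde", "or_nie")) {
    expect_equal(unname(f[nm]), tr[[nm]], tolerance = 0.01)
  }
})

test_that("proportion mediated follows the log-ratio definition with guarded edges", {
  expect_equal(proportion_mediated(1.23, 4.09), log(1.23) / log(4.09),
               tolerance = 1e-14)
  expect_identical(proportion_mediated(1.00, 2.50), 0)
  expect_warning(pm_null <- proportion_mediated(1.1, 1), "undefined")
  expect_true(is.na(pm_null))
  expect_warning(proportion_mediated(0.8, 1.5), "opposite")
  expect_error(proportion_mediated(-1, 2))
  # invariance under jointly raising both ORs to a power
  for (k in c(0.5, 2, 3.7)) {
    expect_equal(proportion_mediated(1.2^k, 3.1^k),
                 proportion_mediated(1.2, 3.1), tolerance = 1e-12)
  }
})

test_that("run_mediation recovers effects and satisfies the decomposition identity", {
  p <- recovery_params()
  ch <- generate_cohort(p, 2e4, seed = 31)
  spec <- mediation_spec("sae_lifetime", "heavy_tobacco", "depression")
  est <- run_mediation(ch, spec)
  eff <- est$effects
  expect_equal(eff$or[1], eff$or[2] * eff$or[3], tolerance = 1e-10)
  expect_true(all(is.finite(eff$or)))
  expect_equal(est$pm, log(eff$or[3]) / log(eff$or[1]), tolerance = 1e-12)
  expect_identical(est$n_used, nrow(ch))
  # rough agreement with the oracle at this moderate n
  tr <- true_effects(p, "weighted_mean")
  expect_equal(log(eff$or[1]), log(tr$or_te), tolerance = 0.15)
})

test_that("swapping mediator and outcome runs the reverse-direction analysis", {
  p <- cohort_params("female")
  ch <- generate_cohort(p, 8000, seed = 13)
  fwd <- run_mediation(ch, mediation_spec("sae_lifetime", "heavy_tobacco",
                                          "depression"))
  rev <- run_mediation(ch, mediation_spec("sae_lifetime", "depression",
                                          "heavy_tobacco"))
  expect_identical(rev$spec$mediator, "depression")
  expect_true(all(is.finite(rev$effects$or)))
  expect_false(isTRUE(all.equal(fwd$effects$or, rev$effects$or)))
})

test_that("listwise deletion drives per-cell sample sizes and empty classes error", {
  p <- cohort_params("female")
  ch <- generate_cohort(p, 6000, seed = 17)
  ch <- inject_missingness(ch, seed = 23)  # default per-variable rates
  est_alc <- run_mediation(ch, mediation_spec("sae_lifetime",
                                              "hazardous_alcohol", "depression"))
  est_tob <- run_mediation(ch, mediation_spec("sae_lifetime",
                                              "heavy_tobacco", "depression"))
  cc <- function(v) sum(stats::complete.cases(ch[c("sae_lifetime", v,
                                                   "depression", "age_group",
                                                   "education")]))
  expect_identical(est_alc$n_used, cc("hazardous_alcohol"))
  expect_identical(est_tob$n_used, cc("heavy_tobacco"))
  expect_true(est_alc$n_used < est_tob$n_used)

  ch0 <- ch
  ch0$sae_lifetime <- 0L
  expect_error(run_mediation(ch0, mediation_spec("sae_lifetime",
                                                 "heavy_tobacco", "depression")),
               "exposure class")
})

test_that("covariate evaluation points behave as declared", {
  p <- cohort_params("female")
  ch <- generate_cohort(p, 4000, seed = 19)
  cs_mean <- covariate_setting(ch, c("age_group", "education"), ch$weight,
                               method = "weighted_mean")
  expect_length(cs_mean, 7)
  expect_true(all(cs_mean > 0 & cs_mean < 1))
  cs_modal <- covariate_setting(ch, c("age_group", "education"), ch$weight,
                                method = "modal")
  expect_true(all(cs_modal %in% c(0, 1)))
  # the modal cell is the weighted-majority (age, education) combination
  tab <- tapply(ch$weight, list(ch$age_group, ch$education), sum)
  best <- which(tab == max(tab), arr.ind = TRUE)
  lev_age <- rownames(tab)[best[1]]
  if (lev_age != levels(ch$age_group)[1]) {
    expect_identical(unname(cs_modal[paste0("age_group", lev_age)]), 1)
  }
})
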