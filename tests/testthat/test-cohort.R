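test_that("generation is deterministic given (params, n, seed)", {
  p <- cohort_params("female")
  a <- generate_cohort(p, 1000, seed = 7)
  b <- generate_cohort(p, 1000, seed = 7)
  expect_identical(a, b)
  c <- generate_cohort(p, 1000, seed = 8)
  expect_false(identical(a$sae_lifetime, c$sae_lifetime))
})

test_that("cohort structure: nesting, weights, nested exposure flags", {
  p <- cohort_params("male")
  ch <- generate_cohort(p, 5000, seed = 3)
  # psu ids nest within strata
  expect_true(all(tapply(ch$stratum, ch$psu, function(s) length(unique(s))) == 1))
  expect_true(all(ch$weight > 0))
  expect_equal(mean(ch$weight), 1, tolerance = 1e-12)
  # childhood and repeated exposure are subsets of lifetime exposure
  expect_true(all(ch$sae_lifetime[ch$sae_childhood == 1] == 1))
  expect_true(all(ch$sae_lifetime[ch$sae_repeated == 1] == 1))
  expect_true(all(ch$sae_lifetime %in% 0:1))
  expect_error(generate_cohort(p, 0, seed = 1))
})

test_that("null structural model yields a null exposure-outcome association", {
  p <- cohort_params("female",
                     mediator_model = list(exposure = 0),
                     outcome_model = list(exposure = 0, mediator = 0,
                                          interaction = 0))
  ch <- generate_cohort(p, 1e5, seed = 11)
  tab <- table(ch$sae_lifetime, ch[[p$outcome_name]])
  log_or <- log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1]))
  se <- sqrt(sum(1 / tab))
  expect_lt(abs(log_or), 3 * se)
})

test_that("mediator prevalence matches its closed-form expectation", {
  p <- cohort_params("female")
  n <- 1e5
  ch <- generate_cohort(p, n, seed = 5)
  # closed-form expectation over the finite covariate support, averaged
  # over the exposure distribution
  cells <- expand.grid(age = 1:6, edu = 1:3)
  prob_c <- p$age_probs[cells$age] * p$edu_probs[cells$edu]
  lp <- function(cv) c(0, cv[1:5])[cells$age] + c(0, cv[6:7])[cells$edu]
  p_a <- plogis(p$exposure_model$intercept + lp(p$exposure_model$covariates))
  mm <- p$mediator_model
  expected <- sum(prob_c * (
    (1 - p_a) * plogis(mm$intercept + lp(mm$covariates)) +
      p_a * plogis(mm$intercept + mm$exposure + lp(mm$covariates))))
  mc_se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(ch[[p$mediator_name]]) - expected), 3 * mc_se)
})

test_that("missingness injection is MCAR at the requested rate and deterministic", {
  p <- cohort_params("female")
  ch <- generate_cohort(p, 1e5, seed = 2)

  same <- inject_missingness(ch, rates = c(depression = 0), seed = 9)
  expect_identical(same$depression, ch$depression)

  m1 <- inject_missingness(ch, rates = c(heavy_tobacco = 0.03), seed = 9)
  frac <- mean(is.na(m1$heavy_tobacco))
  expect_lt(abs(frac - 0.03), 3 * sqrt(0.03 * 0.97 / nrow(ch)))

  m2 <- inject_missingness(ch, rates = c(heavy_tobacco = 0.03), seed = 9)
  expect_identical(m1$heavy_tobacco, m2$heavy_tobacco)

  expect_error(inject_missingness(ch, rates = c(heavy_tobacco = 1.2), seed = 1))
  expect_error(inject_missingness(ch, rates = c(nonexistent = 0.1), seed = 1))
  expect_warning(inject_missingness(ch, rates = c(heavy_tobacco = 0.2), seed = 1),
                 "0.05")
})

test_that("cohort CSV round-trips with its parameter and truth sidecar", {
  p <- cohort_params("male")
  ch <- generate_cohort(p, 200, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(ch), tolerance = 1e-12,
               ignore_attr = TRUE)
  tr <- cohort_truth(back)
  expect_equal(tr$or_te, cohort_truth(ch)$or_te, tolerance = 1e-12)
  p_back <- attr(back, "params")
  expect_equal(p_back$outcome_model$intercept, p$outcome_model$intercept,
               tolerance = 1e-12)
})
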