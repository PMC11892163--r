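test_that("percentile interval follows linear interpolation between order statistics", {
  expect_identical(unname(percentile_ci(rep(3.2, 50))), c(3.2, 3.2))
  ci <- percentile_ci(1:1000)
  expect_equal(unname(ci), c(25.975, 975.025), tolerance = 1e-10)
  # widening the level widens the interval
  ci99 <- percentile_ci(1:1000, level = 0.99)
  expect_lt(ci99[["low"]], ci[["low"]])
  expect_gt(ci99[["high"]], ci[["high"]])
  expect_error(percentile_ci(c(1, NA, Inf)), "finite")
})

test_that("resampling is deterministic in (seed, replicate) and respects the design", {
  p <- cohort_params("female")
  ch <- generate_cohort(p, 2000, seed = 51)
  cfg <- bootstrap_config(replicates = 10, seed = 99)
  r1 <- resample_cohort(ch, config = cfg, replicate = 3)
  r2 <- resample_cohort(ch, config = cfg, replicate = 3)
  expect_identical(r1, r2)
  r3 <- resample_cohort(ch, config = cfg, replicate = 4)
  expect_false(identical(r1$weight, r3$weight))

  # PSU resampling keeps whole clusters: every resampled PSU appears with
  # all of its member records
  counts_orig <- table(ch$psu)
  counts_res <- table(r1$psu)
  multiples <- counts_res / counts_orig[names(counts_res)]
  expect_true(all(multiples == round(multiples)))
})

test_that("mean resampled size over replicates is close to the original n", {
  p <- cohort_params("female")
  ch <- generate_cohort(p, 2000, seed = 53)
  cfg <- bootstrap_config(replicates = 200, seed = 7)
  sizes <- vapply(1:200, function(b) nrow(resample_cohort(ch, config = cfg,
                                                          replicate = b)),
                  numeric(1))
  expect_lt(abs(mean(sizes) - nrow(ch)) / nrow(ch), 0.02)
})

test_that("a single-PSU stratum falls back to iid resampling of its rows", {
  d <- tibble::tibble(
    stratum = rep(c(1, 2), each = 20),
    psu = c(rep(1, 20), rep(2:5, each = 5)),
    weight = 1, x = 1:40
  )
  r <- resample_cohort(d, config = bootstrap_config(replicates = 2, seed = 5),
                       replicate = 1)
  expect_identical(nrow(r), 40L)
  expect_identical(sum(r$stratum == 1), 20L)
})

test_that("iid mode equals psu mode when every record is its own PSU", {
  d <- tibble::tibble(stratum = 1L, psu = 1:50, weight = 1, x = rnorm(50))
  cfg_psu <- bootstrap_config(replicates = 2, seed = 31, resampling = "psu")
  cfg_iid <- bootstrap_config(replicates = 2, seed = 31, resampling = "iid")
  r_psu <- resample_cohort(d, config = cfg_psu, replicate = 1)
  r_iid <- resample_cohort(d, config = cfg_iid, replicate = 1)
  # same RNG stream, same index distribution; with one record per PSU the
  # PSU draw is a draw of rows
  expect_identical(sort(table(r_psu$psu)), sort(table(r_iid$psu)))
})

test_that("bootstrap fills intervals deterministically and brackets the point", {
  p <- cohort_params("female")
  ch <- generate_cohort(p, 3000, seed = 55)
  spec <- mediation_spec("sae_lifetime", "heavy_tobacco", "depression")
  cfg <- bootstrap_config(replicates = 60, seed = 13)
  est1 <- bootstrap_mediation(ch, spec, config = cfg)
  est2 <- bootstrap_mediation(ch, spec, config = cfg)
  expect_identical(est1$effects, est2$effects)
  expect_identical(est1$pm_ci, est2$pm_ci)
  expect_identical(est1$n_bootstrap_ok, 60L)
  eff <- est1$effects
  expect_true(all(eff$ci_low <= eff$ci_high))
  expect_true(all(is.finite(c(eff$ci_low, eff$ci_high))))
  expect_type(nie_significant(est1), "logical")
})

test_that("a two-replicate bootstrap gives the degenerate two-point percentile interval", {
  p <- cohort_params("female")
  ch <- generate_cohort(p, 2500, seed = 57)
  spec <- mediation_spec("sae_lifetime", "heavy_tobacco", "depression")
  cfg <- bootstrap_config(replicates = 2, seed = 3)
  est <- bootstrap_mediation(ch, spec, config = cfg)
  # reconstruct the two replicate TE values by hand and compare
  te_reps <- vapply(1:2, function(b) {
    r <- resample_cohort(ch, config = cfg, replicate = b)
    run_mediation(r, spec)$effects$or[1]
  }, numeric(1))
  expect_equal(unname(c(est$effects$ci_low[1], est$effects$ci_high[1])),
               unname(percentile_ci(te_reps)), tolerance = 1e-8)
  expect_true(est$effects$ci_low[1] >= min(te_reps) - 1e-8)
  expect_true(est$effects$ci_high[1] <= max(te_reps) + 1e-8)
})

test_that("widespread replicate failure raises an error naming the tally", {
  # all 4 outcome events sit in 2 of the 20 PSUs of stratum 1; about 12%
  # of PSU resamples lose the outcome class entirely, far above the 5%
  # failure budget
  d <- tibble::tibble(
    stratum = rep(1:10, each = 40),
    psu = rep(1:200, each = 2),
    weight = 1,
    a = rep(c(0L, 0L, 1L, 1L), 100),
    m = rep(c(0L, 1L), 200),
    y = c(rep(1L, 4), rep(0L, 396))
  )
  spec <- mediation_spec("a", "m", "y", covariates = character())
  expect_error(
    bootstrap_mediation(d, spec, config = bootstrap_config(replicates = 50,
                                                           seed = 61)),
    "replicates succeeded")
})

test_that("under a null indirect effect the NIE interval contains 1 at about
           the nominal rate", {
  p0 <- null_mediation_params()
  spec <- mediation_spec("sae_lifetime", "heavy_tobacco", "depression")
  n_outer <- 120
  contains_one <- vapply(seq_len(n_outer), function(i) {
    ch <- generate_cohort(p0, 2500, seed = 40000 + i)
    est <- bootstrap_mediation(ch, spec,
                               config = bootstrap_config(replicates = 200,
                                                         seed = 41000 + i))
    nie <- est$effects[est$effects$effect == "natural_indirect", ]
    nie$ci_low <= 1 && 1 <= nie$ci_high
  }, logical(1))
  expect_gte(mean(contains_one), 0.89)
})
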