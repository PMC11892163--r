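#' Bootstrap configuration
#'
#' @param replicates Number of bootstrap samples (default 1000).
#' @param seed Integer seed. Each replicate's random-number stream is
#'   derived from `(seed, replicate_index)`, so a given replicate is
#'   identical regardless of execution order.
#' @param resampling `"psu"` (default): within each stratum, sample primary
#'   sampling units with replacement up to the original PSU count, carrying
#'   all member records and their weights — honoring the clustering and
#'   stratification of the design. `"iid"`: sample rows with replacement.
#' @param min_success_fraction Minimum fraction of replicates that must
#'   yield a usable estimate (default 0.95); below it, interval estimation
#'   errors rather than reporting intervals from a biased subset.
#' @return A `bootstrap_config`.
#' @export
bootstrap_config <- function(replicates = 1000, seed = 1,
                             resampling = c("psu", "iid"),
                             min_success_fraction = 0.95) {
  resampling <- arg_match(resampling)
  stopifnot(replicates >= 2, min_success_fraction > 0,
            min_success_fraction <= 1)
  structure(list(replicates = as.integer(replicates), seed = as.integer(seed),
                 resampling = resampling,
                 min_success_fraction = min_success_fraction),
            class = "bootstrap_config")
}

# Deterministic per-replicate seed; stays within 32-bit integer range and
# within exact double arithmetic.
replicate_seed <- function(seed, replicate_index) {
  as.integer(((seed %% 2147483647) * 69069 + replicate_index) %% 2147483647)
}

# Precomputed grouping of row indices: per stratum, the list of PSU member
# index vectors. Built once, reused across replicates.
build_resample_plan <- function(stratum, psu, mode) {
  n <- length(stratum)
  if (mode == "iid") return(list(mode = "iid", n = n))
  strata <- lapply(unique(stratum), function(h) {
    rows_h <- which(stratum == h)
    split(rows_h, psu[rows_h])
  })
  list(mode = "psu", n = n, strata = strata)
}

# Row indices of one bootstrap resample. PSU mode: within each stratum,
# sample PSUs with replacement to the original PSU count; a single-PSU
# stratum falls back to iid resampling of its rows.
resample_from_plan <- function(plan) {
  if (plan$mode == "iid") return(sample.int(plan$n, plan$n, replace = TRUE))
  idx_out <- lapply(plan$strata, function(members) {
    if (length(members) < 2) {
      rows_h <- members[[1]]
      rows_h[sample.int(length(rows_h), length(rows_h), replace = TRUE)]
    } else {
      pick <- sample.int(length(members), length(members), replace = TRUE)
      unlist(members[pick], use.names = FALSE)
    }
  })
  unlist(idx_out, use.names = FALSE)
}

resample_indices <- function(stratum, psu, mode) {
  resample_from_plan(build_resample_plan(stratum, psu, mode))
}

#' Draw one design-respecting bootstrap resample
#'
#' @param data Individual records.
#' @param design A [survey_design()].
#' @param config A [bootstrap_config()].
#' @param replicate Replicate index (1-based); together with the config
#'   seed it fully determines the resample.
#' @return A tibble of resampled records (weights carried, not re-derived).
#' @export
resample_cohort <- function(data, design = survey_design(),
                            config = bootstrap_config(), replicate = 1) {
  dv <- design_vectors(data, design)
  idx <- withr::with_seed(
    replicate_seed(config$seed, replicate),
    resample_indices(dv$stratum, dv$psu, config$resampling)
  )
  as_tibble(data[idx, , drop = FALSE])
}

#' Percentile confidence interval
#'
#' Empirical quantiles of the replicate values at the interval tails,
#' using linear interpolation between order statistics (the default
#' sample-quantile definition; recorded in output metadata because
#' percentile dialects differ).
#'
#' @param x Numeric vector of replicate values; non-finite entries are
#'   dropped.
#' @param level Confidence level (default 0.95).
#' @return Named numeric `c(low, high)`.
#' @examples
#' percentile_ci(1:1000)  # c(25.975, 975.025)
#' @export
percentile_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  if (length(x) < 2) abort("need at least 2 finite replicate values")
  alpha <- (1 - level) / 2
  q <- quantile(x, c(alpha, 1 - alpha), type = 7, names = FALSE)
  c(low = q[1], high = q[2])
}

#' Mediation analysis with percentile bootstrap confidence intervals
#'
#' Computes the point estimates with [run_mediation()], then re-runs the
#' entire estimation (both model fits, covariate evaluation, effect
#' combination) on each bootstrap resample and forms percentile intervals
#' for the total, natural direct and natural indirect effect odds ratios
#' and the proportion mediated. Replicates failing through non-convergence,
#' separation, or an empty exposure/response class are dropped and
#' tallied; if fewer than `min_success_fraction` of replicates survive, an
#' error naming the failure tally is raised.
#'
#' An indirect effect is flagged significant when its interval excludes 1.
#'
#' @inheritParams run_mediation
#' @param config A [bootstrap_config()].
#' @param level Confidence level (default 0.95).
#' @return A `mediation_estimate` with `ci_low`/`ci_high` filled,
#'   `pm_ci`, `n_bootstrap_ok`, and a `bootstrap` metadata list
#'   (config echo, failure tally, percentile definition).
#' @export
bootstrap_mediation <- function(data, spec, design = survey_design(),
                                config = bootstrap_config(), level = 0.95) {
  point <- run_mediation(data, spec, design)

  vars <- c(spec$exposure, spec$mediator, spec$outcome, spec$covariates)
  cc <- stats::complete.cases(data[vars])
  data <- data[cc, , drop = FALSE]
  dv <- design_vectors(data, design)
  w <- dv$weight

  # prebuilt design matrices; per replicate only rows are re-indexed
  form_m <- stats::reformulate(c(spec$exposure, spec$covariates))
  rhs_y <- c(spec$exposure, spec$mediator, spec$covariates)
  if (spec$interaction) {
    rhs_y <- c(rhs_y, paste(spec$exposure, spec$mediator, sep = ":"))
  }
  form_y <- stats::reformulate(rhs_y)
  X_m <- model.matrix(form_m, data = data)
  X_y <- model.matrix(form_y, data = data)
  y_m <- as.numeric(data[[spec$mediator]])
  y_y <- as.numeric(data[[spec$outcome]])
  cov_cols <- setdiff(colnames(X_m), c("(Intercept)", spec$exposure))
  X_cov <- X_m[, cov_cols, drop = FALSE]

  start_m <- coef(point$mediator_fit)[colnames(X_m)]
  start_y <- coef(point$outcome_fit)[colnames(X_y)]

  fail <- c(non_convergence = 0L, separation = 0L, degenerate = 0L)
  B <- config$replicates
  ors <- matrix(NA_real_, B, 3)
  pms <- rep(NA_real_, B)
  plan <- build_resample_plan(dv$stratum, dv$psu, config$resampling)

  withr::local_preserve_seed()
  for (b in seq_len(B)) {
    set.seed(replicate_seed(config$seed, b))
    idx <- resample_from_plan(plan)
    ym <- y_m[idx]; yy <- y_y[idx]
    if (length(unique(X_m[idx, spec$exposure])) < 2 ||
        length(unique(ym)) < 2 || length(unique(yy)) < 2) {
      fail["degenerate"] <- fail["degenerate"] + 1L
      next
    }
    fm <- tryCatch(fit_logistic_mm(X_m[idx, , drop = FALSE], ym, w[idx],
                                   start = start_m),
                   error = function(e) NULL)
    fy <- tryCatch(fit_logistic_mm(X_y[idx, , drop = FALSE], yy, w[idx],
                                   start = start_y),
                   error = function(e) NULL)
    if (is.null(fm) || is.null(fy) || !fm$converged || !fy$converged) {
      fail["non_convergence"] <- fail["non_convergence"] + 1L
      next
    }
    if (fm$separation_detected || fy$separation_detected) {
      fail["separation"] <- fail["separation"] + 1L
      next
    }
    cs <- switch(spec$covariate_evaluation,
      weighted_mean = colSums(X_cov[idx, , drop = FALSE] * w[idx]) / sum(w[idx]),
      modal = covariate_setting(data[idx, , drop = FALSE], spec$covariates,
                                w[idx], method = "modal"),
      explicit = spec$c_setting
    )
    b_lp0 <- fm$coefficients[["(Intercept)"]] +
      if (length(cs)) sum(fm$coefficients[names(cs)] * as.numeric(cs)) else 0
    th3 <- if (spec$interaction) {
      inm <- paste(spec$exposure, spec$mediator, sep = ":")
      if (inm %in% names(fy$coefficients)) fy$coefficients[[inm]]
      else fy$coefficients[[paste(spec$mediator, spec$exposure, sep = ":")]]
    } else 0
    o <- or_formulas(fy$coefficients[[spec$exposure]],
                     fy$coefficients[[spec$mediator]], th3,
                     b_lp0, fm$coefficients[[spec$exposure]])
    ors[b, ] <- o[c("or_te", "or_nde", "or_nie")]
    pms[b] <- if (o[["or_te"]] == 1) NA_real_ else
      log(o[["or_nie"]]) / log(o[["or_te"]])
  }

  ok <- is.finite(ors[, 1])
  n_ok <- sum(ok)
  if (n_ok < config$min_success_fraction * B) {
    abort(paste0(
      "only ", n_ok, "/", B, " bootstrap replicates succeeded (minimum ",
      config$min_success_fraction * B, "); failures: ",
      paste(names(fail), fail, sep = " = ", collapse = ", ")))
  }

  ci <- t(apply(ors, 2, percentile_ci, level = level))
  pm_ci <- if (sum(is.finite(pms)) >= 2) percentile_ci(pms, level) else NULL

  est <- new_mediation_estimate(
    ors = setNames(point$effects$or, c("or_te", "or_nde", "or_nie")),
    pm = point$pm, spec = spec, n_used = point$n_used,
    c_setting = point$c_setting,
    outcome_prevalence = point$outcome_prevalence,
    mediator_prevalence = point$mediator_prevalence,
    outcome_fit = point$outcome_fit, mediator_fit = point$mediator_fit,
    ci = ci, pm_ci = pm_ci, n_bootstrap_ok = n_ok,
    bootstrap = list(config = config, level = level, failures = fail,
                     percentile_definition = "linear interpolation (type 7)")
  )
  est
}

#' Is the natural indirect effect significant?
#'
#' Flags significance by the interval rule: the indirect effect is
#' significant when its 95% bootstrap interval does not contain 1.
#'
#' @param estimate A `mediation_estimate` with intervals filled.
#' @return Logical.
#' @export
nie_significant <- function(estimate) {
  eff <- estimate$effects
  row <- eff[eff$effect == "natural_indirect", ]
  if (is.na(row$ci_low)) abort("intervals not filled; run bootstrap_mediation()")
  row$ci_low > 1 || row$ci_high < 1
}
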