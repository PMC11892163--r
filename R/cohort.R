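AGE_LEVELS <- c("18-25", "26-35", "36-45", "46-55", "56-65", "66-75")
EDU_LEVELS <- c("high", "medium", "low")

#' Generate a synthetic stratified-cluster survey cohort
#'
#' Draws `n` independent records from the structural model in `params`:
#' covariates (age group, education) from their categorical distributions,
#' then exposure, mediator, auxiliary health variables and outcome from the
#' logistic structural equations of the underlying directed acyclic graph
#' (exposure -> mediator -> outcome, with covariates as common causes).
#' A childhood-onset exposure flag is nested inside the lifetime exposure,
#' and a repeated-exposure flag is drawn conditional on exposure, so that
#' sensitivity-analysis contrasts can be formed. Survey-design columns
#' (stratum, PSU nested within stratum, log-normal weights normalized to
#' unit mean) are attached; weights are independent of the variables and
#' exist to exercise design-aware estimation code paths.
#'
#' The exact counterfactual truth implied by `params` (see [true_effects()])
#' is attached as attribute `"truth"`, and `params` as attribute `"params"`;
#' retrieve them with [cohort_truth()].
#'
#' @param params A [cohort_params()] object.
#' @param n Number of records (positive integer).
#' @param seed Integer seed; the draw is fully deterministic given
#'   `(params, n, seed)`.
#' @param include_exclusions If `TRUE`, also simulate the pre-analysis
#'   artefacts removed by [apply_exclusion_flow()]: exposure set missing at
#'   a small rate, and a `sae_recent` flag for exposure within the past 12
#'   months. Default `FALSE` (analytic-style cohort).
#'
#' @return A tibble with columns `sex`, `age_group`, `education`, `stratum`,
#'   `psu`, `weight`, `sae_lifetime`, `sae_childhood`, `sae_repeated`,
#'   `sae_recent`, and one 0/1 column per health variable (by default
#'   `hazardous_alcohol`, `heavy_tobacco`, `frequent_cannabis`,
#'   `depression`).
#'
#' @examples
#' p <- cohort_params("female")
#' ch <- generate_cohort(p, n = 500, seed = 1)
#' cohort_truth(ch)
#' @export
generate_cohort <- function(params, n, seed, include_exclusions = FALSE) {
  stopifnot(inherits(params, "cohort_params"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("`n` must be a positive integer")
  }
  n <- as.integer(n)

  cohort <- withr::with_seed(seed, {
    age <- sample.int(6, n, replace = TRUE, prob = params$age_probs)
    edu <- sample.int(3, n, replace = TRUE, prob = params$edu_probs)

    lp_cov <- function(covariates) {
      age_c <- c(0, covariates[seq_len(5)])
      edu_c <- c(0, covariates[6:7])
      age_c[age] + edu_c[edu]
    }

    em <- params$exposure_model
    a <- rbinom(n, 1L, plogis(em$intercept + lp_cov(em$covariates)))
    childhood <- a * rbinom(n, 1L, params$childhood_given_exposure)
    repeated <- a * rbinom(n, 1L, params$repeated_given_exposure)

    mm <- params$mediator_model
    m <- rbinom(n, 1L, plogis(mm$intercept + mm$exposure * a + lp_cov(mm$covariates)))

    om <- params$outcome_model
    y <- rbinom(n, 1L, plogis(om$intercept + om$exposure * a + om$mediator * m +
                                om$interaction * a * m + lp_cov(om$covariates)))

    aux <- lapply(params$aux_models, function(am) {
      rbinom(n, 1L, plogis(am$intercept + am$exposure * a + lp_cov(am$covariates)))
    })

    des <- params$design
    stratum <- sample.int(des$n_strata, n, replace = TRUE)
    psu_within <- sample.int(des$psus_per_stratum, n, replace = TRUE)
    psu <- (stratum - 1L) * des$psus_per_stratum + psu_within
    w <- rlnorm(n, meanlog = -des$weight_sdlog^2 / 2, sdlog = des$weight_sdlog)
    w <- w / mean(w)

    out <- tibble(
      sex = params$sex,
      age_group = factor(AGE_LEVELS[age], levels = AGE_LEVELS),
      education = factor(EDU_LEVELS[edu], levels = EDU_LEVELS),
      stratum = stratum, psu = psu, weight = w,
      sae_lifetime = a, sae_childhood = childhood, sae_repeated = repeated,
      sae_recent = 0L
    )
    out[[params$mediator_name]] <- m
    for (nm in names(aux)) out[[nm]] <- aux[[nm]]
    out[[params$outcome_name]] <- y

    if (include_exclusions) {
      out$sae_recent <- rbinom(n, 1L, params$recent_rate)
      miss_a <- runif(n) < 0.013
      out$sae_lifetime[miss_a] <- NA_integer_
      out$sae_childhood[miss_a] <- NA_integer_
      out$sae_repeated[miss_a] <- NA_integer_
    }
    out
  })

  attr(cohort, "params") <- params
  attr(cohort, "truth") <- true_effects(params)
  cohort
}

#' Retrieve the generating truth attached to a synthetic cohort
#'
#' @param cohort A tibble produced by [generate_cohort()].
#' @return The `truth_record` attached at generation time (see
#'   [true_effects()]), or `NULL` for data not produced by the generator.
#' @export
cohort_truth <- function(cohort) attr(cohort, "truth")

#' Set values missing completely at random
#'
#' Each eligible cell is independently blanked with its per-column
#' probability, emulating the low, patternless item non-response observed in
#' the survey the generator mirrors (missing completely at random; rates
#' below 5% by default).
#'
#' @param data A data frame.
#' @param rates Named numeric vector of per-column missingness probabilities
#'   in `[0, 1]`; names must be columns of `data`. Defaults to the
#'   `missing_rates` of the generating params when `data` came from
#'   [generate_cohort()].
#' @param seed Integer seed; the pattern is deterministic given
#'   `(data, rates, seed)`.
#' @return `data` with the selected cells set to `NA`; generator attributes
#'   are preserved.
#' @export
inject_missingness <- function(data, rates = NULL, seed) {
  if (is.null(rates)) {
    params <- attr(data, "params")
    if (is.null(params)) abort("`rates` must be given for non-generated data")
    rates <- params$missing_rates
  }
  if (is.null(names(rates)) || !all(names(rates) %in% names(data))) {
    abort("`rates` must be named after columns of `data`")
  }
  if (any(rates < 0 | rates > 1)) abort("`rates` must lie in [0, 1]")
  if (any(rates > 0.05)) {
    warn("missingness rates above 0.05 exceed the default regime")
  }
  withr::with_seed(seed, {
    for (nm in names(rates)) {
      if (rates[[nm]] > 0) {
        hit <- runif(nrow(data)) < rates[[nm]]
        data[[nm]][hit] <- NA
      }
    }
  })
  data
}

#' Write / read a cohort as delimited text with a parameter sidecar
#'
#' `write_cohort()` stores the records as a plain CSV and, when present, the
#' generating `cohort_params` and truth record as a JSON sidecar
#' (`<path>.json`) so test harnesses can recover the ground truth.
#' `read_cohort()` reverses this.
#'
#' @param data A cohort tibble.
#' @param path CSV file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` a
#'   tibble with factor covariates restored (and truth/params attributes
#'   when a sidecar exists).
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data, path)
  params <- attr(data, "params")
  truth <- attr(data, "truth")
  if (!is.null(params) || !is.null(truth)) {
    side <- list(
      params = unclass(params),
      truth = if (!is.null(truth)) unclass(truth)
    )
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("age_group" %in% names(data)) {
    data$age_group <- factor(data$age_group, levels = AGE_LEVELS)
  }
  if ("education" %in% names(data)) {
    data$education <- factor(data$education, levels = EDU_LEVELS)
  }
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$params)) {
      p <- side$params
      for (f in c("exposure_model", "mediator_model", "outcome_model")) {
        p[[f]]$covariates <- unlist(p[[f]]$covariates)
      }
      p$aux_models <- lapply(p$aux_models, function(am) {
        am$covariates <- unlist(am$covariates); am
      })
      p$missing_rates <- unlist(p$missing_rates)
      attr(data, "params") <- structure(p, class = "cohort_params")
    }
    if (!is.null(side$truth)) {
      attr(data, "truth") <- structure(side$truth, class = "truth_record")
    }
  }
  data
}
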