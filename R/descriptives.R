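#' Declare the survey design columns of a cohort table
#'
#' A lightweight pointer to the columns that carry the complex-design
#' information: stratum identifiers, primary sampling unit (PSU)
#' identifiers nested within strata, and per-record sampling weights.
#'
#' @param stratum,psu,weight Column names (strings). Any may be `NULL`:
#'   a `NULL` weight means unit weights, `NULL` stratum/psu mean each
#'   record is its own sampling unit in a single stratum.
#' @return An object of class `survey_design`.
#' @examples
#' des <- survey_design("stratum", "psu", "weight")
#' @export
survey_design <- function(stratum = "stratum", psu = "psu", weight = "weight") {
  structure(list(stratum = stratum, psu = psu, weight = weight),
            class = "survey_design")
}

design_vectors <- function(data, design) {
  n <- nrow(data)
  get_col <- function(nm, default) {
    if (is.null(nm)) return(default)
    if (!nm %in% names(data)) abort(paste0("design column `", nm, "` not found"))
    data[[nm]]
  }
  list(
    stratum = get_col(design$stratum, rep(1L, n)),
    psu = get_col(design$psu, seq_len(n)),
    weight = {
      w <- get_col(design$weight, rep(1, n))
      if (any(!is.na(w) & w <= 0)) abort("weights must be strictly positive")
      w
    }
  )
}

#' Design-based weighted prevalence with a logit-scale confidence interval
#'
#' Estimates the weighted prevalence of a binary variable together with a
#' 95% confidence interval that accounts for the survey design. Records
#' missing the variable are dropped first (complete-case, per-variable).
#' The point estimate is the ratio \eqn{\sum w_i x_i / \sum w_i}; its
#' variance is obtained by Taylor linearization over primary sampling units
#' within strata (with-replacement approximation, the convention of
#' mainstream survey software), and the interval is a Wald interval on the
#' logit scale back-transformed to the probability scale, which keeps it
#' inside \eqn{[0, 1]}.
#'
#' @param data A data frame of individual records.
#' @param variable Name of a 0/1 column.
#' @param design A [survey_design()]; defaults to unit weights and
#'   independent records when columns are absent.
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `variable`, `point`, `ci_low`, `ci_high`,
#'   `n_unweighted` (records used), `n_missing` (records dropped).
#'   A variable constant across the sample yields a degenerate interval
#'   equal to the point.
#' @examples
#' d <- tibble::tibble(x = c(1, 0, 0, 0), w = c(3, 1, 1, 1))
#' weighted_prevalence(d, "x", survey_design(NULL, NULL, "w"))
#' @export
weighted_prevalence <- function(data, variable, design = survey_design(),
                                level = 0.95) {
  if (!variable %in% names(data)) {
    abort(paste0("variable `", variable, "` not found"))
  }
  x <- data[[variable]]
  keep <- !is.na(x)
  n_missing <- sum(!keep)
  data <- data[keep, , drop = FALSE]
  x <- as.numeric(x[keep])
  if (length(x) == 0) abort("no records with a valid value")
  if (!all(x %in% c(0, 1))) abort("`variable` must be binary 0/1")

  dv <- design_vectors(data, design)
  w <- dv$weight
  p <- sum(w * x) / sum(w)

  if (p <= 0 || p >= 1) {
    ci <- c(p, p)
  } else {
    # linearized influence values, aggregated to PSU totals within strata
    u <- w * (x - p) / sum(w)
    psu_tot <- tapply(u, list(dv$stratum, dv$psu), sum)
    v <- 0
    for (h in rownames(psu_tot)) {
      th <- psu_tot[h, ]
      th <- th[!is.na(th)]
      nh <- length(th)
      if (nh >= 2) v <- v + nh / (nh - 1) * sum((th - mean(th))^2)
    }
    if (v <= 0) {
      ci <- c(p, p)
    } else {
      se_logit <- sqrt(v) / (p * (1 - p))
      z <- qnorm(1 - (1 - level) / 2)
      ci <- plogis(qlogis(p) + c(-1, 1) * z * se_logit)
    }
  }

  tibble(variable = variable, point = p, ci_low = ci[1], ci_high = ci[2],
         n_unweighted = length(x), n_missing = n_missing)
}

#' Prevalence table across several variables
#'
#' Applies [weighted_prevalence()] to each variable and stacks the rows,
#' yielding a descriptives table (variable, weighted %, CI bounds,
#' unweighted n, missing count) ready to write as CSV.
#'
#' @inheritParams weighted_prevalence
#' @param variables Character vector of 0/1 columns.
#' @return A tibble with one row per variable.
#' @export
prevalence_table <- function(data, variables, design = survey_design(),
                             level = 0.95) {
  purrr::map_dfr(variables, function(v) {
    weighted_prevalence(data, v, design, level)
  })
}

#' Are two confidence intervals disjoint?
#'
#' The conservative descriptive comparison rule: a difference between two
#' prevalence estimates is flagged only when their confidence intervals do
#' not overlap at all. A shared endpoint counts as overlap (not disjoint).
#'
#' @param a,b Either one-row tibbles with `ci_low`/`ci_high` columns (as
#'   returned by [weighted_prevalence()]) or numeric `c(low, high)` pairs.
#' @return `TRUE` iff the closed intervals have empty intersection.
#' @examples
#' ci_disjoint(c(0.10, 0.20), c(0.25, 0.35))  # TRUE
#' ci_disjoint(c(0.10, 0.20), c(0.20, 0.30))  # FALSE: shared endpoint
#' @export
ci_disjoint <- function(a, b) {
  bounds <- function(x) {
    if (is.data.frame(x)) c(x$ci_low[1], x$ci_high[1]) else as.numeric(x[1:2])
  }
  a <- bounds(a); b <- bounds(b)
  if (anyNA(c(a, b))) abort("interval bounds must be non-missing")
  a[2] < b[1] || b[2] < a[1]
}

#' Apply the pre-analysis respondent exclusion flow
#'
#' Removes, in order: (1) records with no exposure information (missing
#' lifetime-exposure value), then (2) records reporting exposure within the
#' past 12 months, whose mediator/outcome recall window would overlap the
#' exposure. The per-rule counts are attached as attribute `"exclusions"`
#' and available via [exclusion_counts()].
#'
#' @param data A data frame with the exposure column and recent-exposure
#'   flag column.
#' @param exposure Name of the lifetime exposure column (missing = no
#'   exposure information).
#' @param recent Name of the 0/1 recent-exposure flag column.
#' @return The filtered tibble, with `exclusions` attribute
#'   `c(missing_exposure = ..., recent_exposure = ...)`.
#' @examples
#' d <- tibble::tibble(sae_lifetime = c(1, NA, 0), sae_recent = c(0, 0, 1))
#' exclusion_counts(apply_exclusion_flow(d))
#' @export
apply_exclusion_flow <- function(data, exposure = "sae_lifetime",
                                 recent = "sae_recent") {
  for (nm in c(exposure, recent)) {
    if (!nm %in% names(data)) abort(paste0("column `", nm, "` not found"))
  }
  miss <- is.na(data[[exposure]])
  n_miss <- sum(miss)
  data <- data[!miss, , drop = FALSE]
  rec <- !is.na(data[[recent]]) & data[[recent]] == 1
  n_rec <- sum(rec)
  data <- data[!rec, , drop = FALSE]
  out <- as_tibble(data)
  attr(out, "exclusions") <- c(missing_exposure = n_miss, recent_exposure = n_rec)
  out
}

#' @rdname apply_exclusion_flow
#' @export
exclusion_counts <- function(data) attr(data, "exclusions")
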