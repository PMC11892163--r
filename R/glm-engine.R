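# Low-level weighted logistic fit on a prebuilt model matrix. Weights are
# frequency-style multipliers of the log-likelihood (pseudo-likelihood);
# the compiled IRLS core keeps the heavy bootstrap refitting affordable.
# No model-based standard errors exist here — interval estimation is
# bootstrap-based throughout.
fit_logistic_mm <- function(X, y, w = NULL, start = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  fit <- .irls_logistic(X, as.numeric(y), as.numeric(w),
                        start = start, tol = 1e-8, maxit = 100L)
  cf <- setNames(drop(fit$coefficients), colnames(X))
  list(coefficients = cf, converged = fit$converged,
       separation_detected = fit$separation, n_used = length(y),
       fitted_range = c(fit$fitted_min, fit$fitted_max))
}

#' Fit a survey-weighted logistic regression
#'
#' Fits a logistic model by maximizing the weight-multiplied log-likelihood
#' (iteratively reweighted least squares, relative tolerance 1e-8, at most
#' 100 iterations). Records missing any model variable are excluded first
#' (listwise deletion). Categorical terms are indicator-coded against their
#' first factor level. Coefficients are invariant to positive rescaling of
#' the weights; model-based standard errors are deliberately not exposed —
#' interval estimation belongs to [bootstrap_mediation()].
#'
#' Complete or quasi-complete separation is flagged (any fitted probability
#' within 1e-8 of 0/1 at convergence, or a coefficient beyond 15 on the
#' logit scale) rather than erroring, so that bootstrap replicates can be
#' dropped while point estimation can refuse loudly.
#'
#' @param data A data frame.
#' @param response Name of the 0/1 response column.
#' @param terms Character vector of predictor columns (numeric or factor).
#' @param weights Name of a positive weight column, or `NULL` for unit
#'   weights.
#' @param interaction Optional length-2 character vector naming two columns
#'   of `terms` whose product term is added (e.g. exposure-by-mediator).
#' @return A `logistic_fit`: named coefficient vector on the logit scale,
#'   `converged` and `separation_detected` flags, `n_used`, and the term
#'   metadata needed by [predict_prob()].
#' @examples
#' d <- tibble::tibble(y = rbinom(100, 1, 0.3), x = rbinom(100, 1, 0.5))
#' fit_weighted_logistic(d, "y", "x")
#' @export
fit_weighted_logistic <- function(data, response, terms, weights = NULL,
                                  interaction = NULL) {
  vars <- unique(c(response, terms, weights))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    abort(paste0("columns not found: ", paste(missing_cols, collapse = ", ")))
  }
  cc <- stats::complete.cases(data[vars])
  data <- data[cc, , drop = FALSE]

  y <- as.numeric(data[[response]])
  if (!all(y %in% c(0, 1))) abort("`response` must be binary 0/1")
  if (length(unique(y)) < 2) {
    abort("response is constant after listwise deletion; model is degenerate")
  }
  w <- if (is.null(weights)) NULL else data[[weights]]
  if (!is.null(w) && any(w <= 0)) abort("weights must be strictly positive")

  rhs <- terms
  if (!is.null(interaction)) {
    stopifnot(length(interaction) == 2, all(interaction %in% terms))
    rhs <- c(rhs, paste(interaction, collapse = ":"))
  }
  form <- stats::reformulate(rhs)
  X <- model.matrix(form, data = data)

  raw <- fit_logistic_mm(X, y, w)
  if (!raw$converged) {
    warn("IRLS did not converge within 100 iterations; estimates returned")
  }
  structure(
    list(coefficients = raw$coefficients, converged = raw$converged,
         separation_detected = raw$separation_detected, n_used = raw$n_used,
         response = response, terms = terms, interaction = interaction,
         formula = form,
         xlevels = lapply(Filter(is.factor, data[terms]), levels)),
    class = "logistic_fit"
  )
}

#' Construct a logistic fit from known coefficients
#'
#' Builds a `logistic_fit` object directly from a named coefficient vector,
#' bypassing estimation. Useful for evaluating the mediation formulas at
#' known (e.g. generating) coefficients.
#'
#' @param coefficients Named numeric vector; must include `"(Intercept)"`.
#' @param response,terms,interaction Metadata as in
#'   [fit_weighted_logistic()].
#' @return A `logistic_fit`.
#' @export
logistic_fit <- function(coefficients, response = "y", terms = names(coefficients),
                         interaction = NULL) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            "(Intercept)" %in% names(coefficients))
  structure(
    list(coefficients = coefficients, converged = TRUE,
         separation_detected = FALSE, n_used = NA_integer_,
         response = response, terms = setdiff(terms, "(Intercept)"),
         interaction = interaction, formula = NULL, xlevels = list()),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit>", x$response, "~",
      paste(c(x$terms, if (!is.null(x$interaction))
        paste(x$interaction, collapse = ":")), collapse = " + "), "\n")
  cat("  n =", x$n_used, " converged:", x$converged,
      " separation:", x$separation_detected, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' Predicted probability at a covariate setting
#'
#' Evaluates the inverse-logit of the linear predictor at one setting of the
#' model terms. The setting may be a one-row data frame (factor levels
#' resolved through the fit's stored coding) or a named numeric vector over
#' the design columns, in which case fractional indicator values (e.g.
#' covariate means) are allowed.
#'
#' @param fit A `logistic_fit`.
#' @param setting One-row data frame supplying every model term, or a named
#'   numeric vector over non-intercept design-matrix columns.
#' @return A probability in (0, 1).
#' @examples
#' f <- logistic_fit(c("(Intercept)" = log(1 / 9)))
#' predict_prob(f, tibble::tibble(.rows = 1))  # 0.1
#' @export
predict_prob <- function(fit, setting) {
  stopifnot(inherits(fit, "logistic_fit"))
  cf <- fit$coefficients
  if (is.data.frame(setting)) {
    missing_terms <- setdiff(fit$terms, names(setting))
    if (length(missing_terms)) {
      abort(paste0("setting lacks model terms: ",
                   paste(missing_terms, collapse = ", ")))
    }
    for (nm in names(fit$xlevels)) {
      setting[[nm]] <- factor(setting[[nm]], levels = fit$xlevels[[nm]])
    }
    if (length(fit$terms)) {
      form <- fit$formula %||% stats::reformulate(fit$terms)
      X <- model.matrix(form, data = setting)
      lp <- drop(X %*% cf[colnames(X)])
    } else {
      lp <- cf[["(Intercept)"]]
    }
  } else {
    setting <- setting[names(setting) != "(Intercept)"]
    unknown <- setdiff(names(setting), names(cf))
    if (length(unknown)) {
      abort(paste0("unknown design columns: ", paste(unknown, collapse = ", ")))
    }
    lp <- cf[["(Intercept)"]] +
      sum(cf[names(setting)] * as.numeric(setting))
  }
  plogis(unname(lp))
}

#' @method tidy logistic_fit
#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         odds_ratio = exp(unname(x$coefficients)))
}
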