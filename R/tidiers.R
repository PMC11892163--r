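#' Tidy a mediation estimate
#'
#' One row per effect (total, natural direct, natural indirect) with the
#' odds ratio and, when the bootstrap has run, the percentile interval.
#' The proportion mediated is appended as a final row on its own scale.
#'
#' @param x A `mediation_estimate`.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `ci_low`, `ci_high`.
#' @method tidy mediation_estimate
#' @export
tidy.mediation_estimate <- function(x, ...) {
  eff <- x$effects
  out <- tibble(term = paste0("or_", c("te", "nde", "nie")),
                estimate = eff$or, ci_low = eff$ci_low, ci_high = eff$ci_high)
  bind_rows(out, tibble(
    term = "proportion_mediated", estimate = x$pm,
    ci_low = if (is.null(x$pm_ci)) NA_real_ else x$pm_ci[["low"]],
    ci_high = if (is.null(x$pm_ci)) NA_real_ else x$pm_ci[["high"]]
  ))
}

#' One-row summary of a mediation estimate
#'
#' @param x A `mediation_estimate`.
#' @param ... Unused.
#' @return A one-row tibble: ORs, PM, sample size, bootstrap bookkeeping
#'   and outcome prevalence (for judging the rare-outcome approximation).
#' @method glance mediation_estimate
#' @export
glance.mediation_estimate <- function(x, ...) {
  eff <- x$effects
  tibble(
    or_te = eff$or[1], or_nde = eff$or[2], or_nie = eff$or[3],
    pm = x$pm, n_used = x$n_used, n_bootstrap_ok = x$n_bootstrap_ok,
    outcome_prevalence = x$outcome_prevalence,
    mediator_prevalence = x$mediator_prevalence,
    interaction = x$spec$interaction,
    covariate_evaluation = x$spec$covariate_evaluation
  )
}

#' Forest-style plot of natural-effect odds ratios
#'
#' @param object A `mediation_estimate` (intervals shown when present).
#' @param ... Unused.
#' @return A ggplot: odds ratios on a log scale with the null line at 1.
#' @method autoplot mediation_estimate
#' @export
autoplot.mediation_estimate <- function(object, ...) {
  eff <- object$effects
  eff$effect <- factor(eff$effect,
                       levels = rev(c("total", "natural_direct",
                                      "natural_indirect")))
  p <- ggplot2::ggplot(eff, ggplot2::aes(x = .data$or, y = .data$effect)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 2)
  if (!all(is.na(eff$ci_low))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.15)
  }
  p + ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Odds ratio (log scale)", y = NULL,
      title = paste(object$spec$exposure, "→", object$spec$mediator,
                    "→", object$spec$outcome),
      subtitle = if (object$pm_undefined) "PM undefined (null total effect)"
      else sprintf("Proportion mediated: %.1f%%", 100 * object$pm)
    ) +
    ggplot2::theme_minimal()
}

#' Plot results of a full analysis grid
#'
#' Faceted forest plot of the total, direct and indirect effect odds
#' ratios for every cell of a [run_grid()] result.
#'
#' @param results The `results` tibble of [run_grid()].
#' @return A ggplot.
#' @export
plot_grid_results <- function(results) {
  long <- tidyr::pivot_longer(
    results,
    cols = c("or_te", "or_nde", "or_nie"),
    names_to = "effect", values_to = "or"
  )
  long$effect <- factor(long$effect, levels = c("or_te", "or_nde", "or_nie"),
                        labels = c("TE", "NDE", "NIE"))
  long$cell <- paste(long$mediator, "→", long$outcome)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$or, y = .data$cell,
                                     colour = .data$effect)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(contrast ~ sex) +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL, colour = "Effect") +
    ggplot2::theme_minimal()
}
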