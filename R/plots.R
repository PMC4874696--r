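# ggplot2 visualizations of fitted objects and benchmark results.

#' Coefficient plot of a multiple logistic regression fit
#'
#' Dot-and-interval plot of the slope estimates; positive betas push bins
#' toward border status, negative betas away from it. L1 fits (no standard
#' errors) are drawn without intervals.
#'
#' @param object A `tad_mlr`.
#' @param intercept Include the intercept? Default `FALSE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tad_mlr
#' @export
autoplot.tad_mlr <- function(object, intercept = FALSE, ...) {
  d <- tidy(object, intercept = intercept)
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$estimate,
    y = stats::reorder(.data$term, .data$estimate)
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "beta (log-odds per unit feature value)",
                  y = NULL,
                  title = sprintf("Multiple logistic regression (%s)",
                                  object$estimator)) +
    ggplot2::theme_minimal()
  if (!is.null(d$conf.low)) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2
    )
  }
  p
}

#' Enrichment-scan plot
#'
#' @param object A `tad_enrichment` from [enrichment_scan()].
#' @param ... Unused.
#' @return A ggplot object: marginal enrichment betas with 95% intervals,
#'   colored by Bonferroni significance.
#' @method autoplot tad_enrichment
#' @export
autoplot.tad_enrichment <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), !is.na(.data$estimate))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$estimate,
    y = stats::reorder(.data$feature, .data$estimate),
    colour = .data$significant
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "enrichment beta = ln(odds ratio)", y = NULL,
                  colour = "Bonferroni\nsignificant",
                  title = "Marginal enrichment at TAD borders") +
    ggplot2::theme_minimal()
}

#' Benchmark summary plot
#'
#' @param object A `tad_benchmark` from [run_comparison()].
#' @param ... Unused.
#' @return A ggplot object: rank-first and family-wise type-I error rates
#'   per method.
#' @method autoplot tad_benchmark
#' @export
autoplot.tad_benchmark <- function(object, ...) {
  d <- tidyr::pivot_longer(object$summary, -"method",
                           names_to = "metric", values_to = "percent")
  d <- dplyr::filter(d, !is.na(.data$percent))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$percent,
                                  fill = .data$method)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = NULL, y = "percent of replicates",
                  title = sprintf("Method comparison (odds ratio %.3g)",
                                  object$target_or)) +
    ggplot2::theme_minimal()
}

#' True-versus-estimated parameter scatter
#'
#' The parameter-recovery diagnostic: one point per (true, estimated)
#' coefficient pair pooled over simulation replicates, the identity line,
#' and the recovery R-squared in the subtitle.
#'
#' @param true,est Numeric vectors of true and estimated parameters.
#' @return A ggplot object.
#' @export
plot_recovery <- function(true, est) {
  r2 <- recovery_r2(true, est)
  ggplot2::ggplot(tibble(true = true, est = est),
                  ggplot2::aes(x = .data$true, y = .data$est)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "true beta", y = "estimated beta",
                  title = "Parameter recovery",
                  subtitle = sprintf("R² = %.1f%%", r2)) +
    ggplot2::theme_minimal()
}
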