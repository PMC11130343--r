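#' Forest plot of marginal means or adjusted means
#'
#' @param means A tibble from [marginal_means()], [adjusted_mean()] or a
#'   per-category table from [run_pipeline()] (needs `estimate`, `conf.low`,
#'   `conf.high` and a label column).
#' @param label Name of the label column (default the first of
#'   `factor_category`, `level` found).
#' @return A ggplot object.
#' @export
plot_forest <- function(means, label = NULL) {
  if (is.null(label)) {
    label <- intersect(c("factor_category", "level", "term"),
                       names(means))[1]
  }
  if (is.na(label)) stop("no label column found", call. = FALSE)
  means <- dplyr::filter(means, !is.na(.data$estimate))
  ggplot2::ggplot(means,
                  ggplot2::aes(x = .data$estimate,
                               y = stats::reorder(.data[[label]],
                                                  .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Effect size (log response ratio)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Funnel plot of residuals against sampling standard errors
#'
#' @param x A `meta_fit` object or a [funnel_data()] tibble.
#' @return A ggplot object with the conventional inverted-SE axis and
#'   pseudo-confidence funnel.
#' @export
plot_funnel <- function(x) {
  dat <- if (inherits(x, "meta_fit")) funnel_data(x) else x
  se_max <- max(dat$std.error) * 1.05
  funnel <- tibble::tibble(
    se = seq(0, se_max, length.out = 50),
    lo = -1.96 * seq(0, se_max, length.out = 50),
    hi = 1.96 * seq(0, se_max, length.out = 50)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$residual,
                                    y = .data$std.error)) +
    ggplot2::geom_line(data = funnel,
                       ggplot2::aes(x = .data$lo, y = .data$se),
                       linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line(data = funnel,
                       ggplot2::aes(x = .data$hi, y = .data$se),
                       linetype = "dotted", colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Residual", y = "Sampling standard error") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Coefficient forest plot of a fitted meta-regression
#'
#' @param object A `meta_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meta_fit <- function(object, ...) {
  plot_forest(tidy(object), label = "term")
}
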