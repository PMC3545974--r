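#' Scatter plot of the PSA cloud on the cost-effectiveness plane
#'
#' Incremental QALYs against incremental costs for every PSA draw, with the
#' willingness-to-pay threshold drawn as a line through the origin.
#'
#' @param psa An `osteo_psa` object.
#' @param wtp Willingness-to-pay threshold (euro per QALY).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = 50000) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- psa$draws
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (EUR)",
                  title = paste(psa$intervention, "vs.", psa$comparator)) +
    ggplot2::theme_minimal()
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param curve Data frame from [acceptability_curve()].
#' @return A ggplot object.
#' @export
plot_acceptability <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$wtp, y = .data$prob)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (EUR per QALY)",
                  y = "Probability cost-effective") +
    ggplot2::theme_minimal()
}
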