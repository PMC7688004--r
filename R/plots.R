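# ggplot2 displays for evaluation results.

#' Observed versus predicted affinities
#'
#' @param object A `loco_result`.
#' @param ... Unused.
#' @return A ggplot: one point per complex, identity line, RMSE and Pearson
#'   r in the subtitle.
#' @export
autoplot.loco_result <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = expression(paste("observed ", Delta, "G (kcal/mol)")),
      y = expression(paste("predicted ", Delta, "G (kcal/mol)")),
      title = "Leave-one-complex-out predictions",
      subtitle = sprintf("n = %d, RMSE = %.2f kcal/mol, Pearson r = %.2f",
                         object$n, object$rmse, object$pearson_r)
    ) +
    ggplot2::theme_minimal()
}

#' Cumulative absolute-error curve
#'
#' @param result A `loco_result` (or anything accepted by
#'   [error_histogram()]).
#' @param bin_edges Error thresholds, kcal/mol.
#' @return A ggplot of the cumulative fraction of complexes predicted
#'   within each absolute error.
#' @export
plot_error_histogram <- function(result, bin_edges = seq(0.5, 5, by = 0.5)) {
  h <- error_histogram(result, bin_edges)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$edge, y = .data$cum_fraction)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "absolute error (kcal/mol)",
                  y = "fraction of complexes within error",
                  title = "Cumulative absolute prediction error") +
    ggplot2::theme_minimal()
}
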