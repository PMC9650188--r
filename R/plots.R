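# ggplot2 displays for the main result types.

#' Plot compressed rhythm curves by group
#'
#' @param curves Tibble with `hour`, `value` and a `group` column.
#' @param value_label Y-axis label.
#' @return A ggplot.
#' @export
plot_rhythm <- function(curves, value_label = "value") {
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$hour, y = .data$value,
                               colour = .data$group)) +
    ggplot2::stat_summary(fun = mean, geom = "line", linewidth = 0.7) +
    ggplot2::labs(x = "clock hour", y = value_label, colour = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curve of an evaluation report
#'
#' @param object A `wear_eval`.
#' @param ... Unused.
#' @return A ggplot of the pooled leave-one-subject-out ROC.
#' @export
autoplot.wear_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false-positive rate", y = "true-positive rate",
      title = sprintf("%s, AUC %.1f%%", object$family, object$metrics$auc)) +
    ggplot2::theme_minimal()
}

#' Normalised feature-importance bars
#'
#' The most important feature is scaled to 100 and the rest adjusted
#' accordingly.
#'
#' @param object A `wear_eval`.
#' @param top_n Number of features to show.
#' @return A ggplot.
#' @export
plot_importance <- function(object, top_n = 10) {
  d <- head(object$importance, top_n)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "relative importance (top = 100)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
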