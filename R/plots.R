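#' Plot a ROC curve
#'
#' @param x An `m6a_metrics` object (with scores), or a ROC tibble from
#'   [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_roc <- function(x, ...) {
  roc <- if (inherits(x, "m6a_metrics")) x$roc else x
  if (is.null(roc)) abort("no ROC points available (were scores supplied?)")
  auc <- if (inherits(x, "m6a_metrics")) x$auc else trapezoid_auc(roc)
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.4f)", auc)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.m6a_metrics <- function(object, ...) plot_roc(object, ...)

#' Plot feature-importance scores
#'
#' Bar chart of the top-ranked features, coloured by the encoder or
#' embedding block each feature came from.
#'
#' @param x An `m6a_importance` (or `m6a_model`, from which the report is
#'   computed).
#' @param top_n Features shown when `x` is a model.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_importance <- function(x, top_n = 20L, ...) {
  imp <- if (inherits(x, "m6a_model")) feature_importance(x, top_n) else x
  stopifnot(inherits(imp, "m6a_importance"))
  df <- imp$features
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$feature, fill = .data$block)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "Importance (gain)", y = NULL, fill = "Block",
      title = sprintf("Top %d features (%.0f%% graph embeddings)",
        nrow(df), 100 * imp$embedding_fraction)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.m6a_importance <- function(object, ...) plot_importance(object, ...)

#' @export
autoplot.m6a_run <- function(object, ...) plot_roc(object$metrics, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
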