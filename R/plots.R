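#' Plot a cross-validation ROC curve
#'
#' Pooled held-out predictions across folds, one ROC curve.
#'
#' @param object `glia_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot glia_cv
#' @export
autoplot.glia_cv <- function(object, ...) {
  m <- compute_metrics(object$predictions$label, object$predictions$prob_activated)
  ggplot2::ggplot(m$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("Pooled CV ROC (%s), AUC = %.3f",
                                  object$modality, m$auc)) +
    ggplot2::theme_minimal()
}

#' Plot the per-epoch training trace
#'
#' Cross-entropy and misclassification loss against epoch.
#'
#' @param object Fitted `glia_model` with a loss trace.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot glia_model
#' @export
autoplot.glia_model <- function(object, ...) {
  tr <- tidy.glia_model(object)
  long <- tidyr::pivot_longer(tr, -"epoch", names_to = "loss", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~loss, scales = "free_y") +
    ggplot2::labs(x = "Epoch", y = NULL, title = "Training losses") +
    ggplot2::theme_minimal()
}

#' Plot KCCA projections by class
#'
#' Scatter of the lifetime-view projection on the two leading canonical
#' directions, coloured by activation state.
#'
#' @param object `glia_kcca` from [kcca_analysis()] (needs `cells`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot glia_kcca
#' @export
autoplot.glia_kcca <- function(object, ...) {
  if (is.null(object$cells)) abort_glia("use kcca_analysis() for a plottable result",
                                        "glia_shape_mismatch")
  df <- object$cells
  df$state <- factor(df$label, c(0, 1), c("resting", "activated"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lifetime_dim1, y = .data$lifetime_dim2,
                                   colour = .data$state)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Canonical direction 1", y = "Canonical direction 2",
                  title = "KCCA projection (lifetime view)") +
    ggplot2::theme_minimal()
}

#' Plot a learning curve
#'
#' @param curve Tibble from [learning_curve()].
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fraction, y = .data$accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Training fraction", y = "Test accuracy") +
    ggplot2::theme_minimal()
}
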