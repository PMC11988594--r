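# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-feature screening significance
#'
#' -log10 ANOVA p-values in canonical feature order, colored by selection.
#'
#' @param object A `voc_screen` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot voc_screen
#' @method autoplot kelp_cnn
#' @export
autoplot.voc_screen <- function(object, ...) {
  df <- tidy(object)
  df$feature_id <- factor(df$feature_id,
                          levels = order_feature_ids(df$feature_id))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$feature_id, y = -log10(pmax(.data$p_value, 1e-300)),
    color = .data$selected
  )) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = -log10(object$alpha), linetype = 2) +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ p),
                  color = sprintf("p < %g", object$alpha),
                  title = "Per-feature one-way ANOVA across origins") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot training curves
#'
#' Per-epoch cross-entropy loss and training accuracy of a fitted model.
#'
#' @param object A trained `kelp_cnn`.
#' @param ... Unused.
#' @return A ggplot (faceted loss/accuracy curves).
#' @method autoplot origin_eval
#' @export
autoplot.kelp_cnn <- function(object, ...) {
  if (is.null(object$history)) {
    stop_kelp("model has no training history yet", class = "kelptrace_argument_error")
  }
  df <- tidyr::pivot_longer(object$history, c("loss", "accuracy"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "1D-CNN training history") +
    ggplot2::theme_minimal()
}

#' Plot one-vs-rest ROC curves
#'
#' @param object An `origin_eval` object.
#' @param ... Unused.
#' @return A ggplot of the per-class ROC curves with AUC labels.
#' @method autoplot kelp_shap
#' @export
autoplot.origin_eval <- function(object, ...) {
  labels <- sprintf("%s (AUC %.2f)", names(object$auc), object$auc)
  df <- object$roc
  df$class <- factor(df$class, levels = names(object$auc), labels = labels)
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr, color = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, color = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  color = NULL, title = "One-vs-rest ROC") +
    ggplot2::theme_minimal()
}

#' Plot stacked global feature importance
#'
#' Mean absolute Shapley value per feature, stacked by origin class, for the
#' top-ranked features.
#'
#' @param object A `kelp_shap` object.
#' @param top_n How many features to show (default 20).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kelp_shap <- function(object, top_n = 20L, ...) {
  imp <- shap_importance(object, top_n = top_n)
  long <- tidyr::pivot_longer(imp, dplyr::starts_with("mean_abs_"),
                              names_to = "class", values_to = "mean_abs_phi",
                              names_prefix = "mean_abs_")
  long$feature_id <- factor(long$feature_id, levels = rev(imp$feature_id))
  ggplot2::ggplot(long, ggplot2::aes(.data$mean_abs_phi, .data$feature_id,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |SHAP value| (probability units)", y = NULL,
                  fill = "origin", title = "Global feature importance") +
    ggplot2::theme_minimal()
}

#' Force-plot style local explanation
#'
#' Horizontal bars for the strongest signed contributions of one prediction,
#' anchored at the class base value.
#'
#' @param force A `shap_force` record from [shap_local()].
#' @param top_n Number of contributions to display (default 10).
#' @return A ggplot.
#' @export
plot_force <- function(force, top_n = 10L) {
  df <- head(force$contributions, top_n)
  df$feature_id <- factor(df$feature_id, levels = rev(df$feature_id))
  ggplot2::ggplot(df, ggplot2::aes(.data$phi, .data$feature_id,
                                   fill = .data$phi > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, color = "grey40") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#d7301f", `FALSE` = "#2b8cbe")) +
    ggplot2::labs(
      x = "SHAP value (probability units)", y = NULL,
      title = sprintf("%s | class %s", force$sample_id, force$class_name),
      subtitle = sprintf("base %.4f -> output %.4f", force$base_value,
                         force$output)
    ) +
    ggplot2::theme_minimal()
}
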