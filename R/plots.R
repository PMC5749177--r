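#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_point
#'   geom_col geom_hline labs scale_fill_gradient2 theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot the training loss curve
#'
#' @param object A `pwmnet_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pwmnet_model <- function(object, ...) {
  ggplot(object$history, aes(x = .data$epoch, y = .data$loss)) +
    geom_line() +
    labs(x = "epoch", y = "mean cross-entropy",
         title = sprintf("Training loss (%s head)", object$config$output)) +
    theme_minimal()
}

#' Heatmap of an importance profile
#'
#' TF-by-position DeepLIFT contributions; positive scores (red) support the
#' targeted output relative to the reference, negative (blue) oppose it.
#'
#' @param object A `pwmnet_importance`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pwmnet_importance <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$position, y = .data$tf_id, fill = .data$score)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    labs(x = "scan position", y = NULL, fill = "score",
         title = sprintf("DeepLIFT importance (target %s)", format(object$target))) +
    theme_minimal()
}

#' Heatmap of a saturation-mutagenesis map
#'
#' Per-position, per-base prediction changes; the reference base of each
#' position is exactly 0.
#'
#' @param object A `pwmnet_mutagenesis`.
#' @param positions Optional integer range of positions to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pwmnet_mutagenesis <- function(object, positions = NULL, ...) {
  d <- tidy(object)
  if (!is.null(positions)) d <- filter(d, .data$position %in% positions)
  ggplot(d, aes(x = .data$position, y = .data$base, fill = .data$delta)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    labs(x = "window position", y = "mutated base",
         fill = expression(Delta * "pred"),
         title = sprintf("Saturation mutagenesis (target %s)", format(object$target))) +
    theme_minimal()
}

#' Scatter plot of predicted allelic effects vs observed imbalance
#'
#' @param object A `pwmnet_imbalance_cor`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pwmnet_imbalance_cor <- function(object, ...) {
  ggplot(object$data, aes(x = .data$delta_median, y = .data$observed_effect)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    labs(x = "predicted delta (median alt - median ref)",
         y = sprintf("observed imbalance (%s)", object$transform),
         title = sprintf("%s r = %.2f (n = %d)", object$method, object$r, object$n)) +
    theme_minimal()
}

#' Bar plot of per-cell-type AUCs, own vs cross-cell-type
#'
#' @param auc_table Output of [evaluate_auc()].
#' @return A ggplot.
#' @export
plot_auc_matrix <- function(auc_table) {
  d <- mutate(auc_table,
              kind = ifelse(.data$score_celltype == .data$label_celltype,
                            "same cell type", "cross cell type"))
  ggplot(d, aes(x = .data$label_celltype, y = .data$auc, fill = .data$kind)) +
    geom_col(position = "dodge") +
    facet_wrap(~score_celltype) +
    geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    labs(x = "labels from", y = "AUC", fill = NULL,
         title = "Predictive accuracy by cell type (scores from each facet)") +
    theme_minimal()
}
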