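#' PCA score plot with QC cluster
#'
#' Scatter of the first two PCA score components, colored by sample
#' role/group, with an ellipse around the pooled-QC injections — the
#' standard at-a-glance check that QCs cluster tightly relative to the
#' study samples.
#'
#' @param scores Output of [pca_scores()].
#' @return A ggplot object.
#' @export
plot_pca <- function(scores) {
  stopifnot(all(c("PC1", "PC2") %in% names(scores)))
  ve <- attr(scores, "var_explained")
  scores$what <- ifelse(scores$role == "sample", scores$group, scores$role)
  p <- ggplot2::ggplot(scores, ggplot2::aes(.data$PC1, .data$PC2,
                                            color = .data$what)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(color = NULL,
                  x = if (!is.null(ve)) sprintf("PC1 (%.1f%%)", 100 * ve[1]) else "PC1",
                  y = if (!is.null(ve)) sprintf("PC2 (%.1f%%)", 100 * ve[2]) else "PC2") +
    ggplot2::theme_minimal()
  if (sum(scores$role == "QC") >= 3) {
    p <- p + ggplot2::stat_ellipse(
      data = scores[scores$role == "QC", ], show.legend = FALSE)
  }
  p
}

#' MA-versus-IR scatter of the sulfate classification
#'
#' The two calculated diagnostics drive the two-class separation:
#' sulfated features mass at high MA and IR (orange), non-sulfated at
#' the origin (black).
#'
#' @param clusters Output of [classify_sulfates()].
#' @return A ggplot object.
#' @export
plot_sulfate_clusters <- function(clusters) {
  stopifnot(all(c("ir", "ma", "label") %in% names(clusters)))
  ggplot2::ggplot(clusters, ggplot2::aes(.data$ir, .data$ma,
                                         color = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_color_manual(
      values = c("sulfated" = "darkorange", "non-sulfated" = "black")) +
    ggplot2::labs(x = "IR (intensity ratio)", y = "MA (% of base peak)",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential result
#'
#' Grey / blue / red encoding of the three-tier categorization:
#' non-significant, mid-significant (adjusted p passes, fold change
#' within +/- 8), significant (both pass).
#'
#' @param object A `sulfo_diff` from [differential_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sulfo_diff
#' @export
autoplot.sulfo_diff <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$neg_log_p <- -log10(pmax(df$adj_p, .Machine$double.xmin))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, .data$neg_log_p,
                                   color = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_color_manual(values = c(
      "non-significant" = "grey60", "mid-significant" = "steelblue",
      "significant" = "red2")) +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = expression(-log[10] ~ "adjusted" ~ italic(p)),
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sulfo_diff
#' @export
plot_volcano <- function(object, ...) autoplot.sulfo_diff(object, ...)

#' Pooled ROC curve of an MCCV report
#'
#' @param object An `mccv_report` from [mccv_rf()].
#' @param ... Unused.
#' @return A ggplot object annotated with the pooled AUC and its 95%
#'   band.
#' @method autoplot mccv_report
#' @export
autoplot.mccv_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey70") +
    ggplot2::geom_step(color = "navy", linewidth = 0.8) +
    ggplot2::annotate(
      "text", x = 0.65, y = 0.15,
      label = sprintf("AUC %.3f (95%% band %.3f-%.3f)", object$auc,
                      object$ci[["lower"]], object$ci[["upper"]])) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mccv_report
#' @export
plot_roc <- function(object, ...) autoplot.mccv_report(object, ...)
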