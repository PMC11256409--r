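#' Plot a PCoA ordination
#'
#' Scatter of samples on the first two principal coordinates with axis
#' labels showing the variance explained; optionally coloured by a grouping
#' with 95% normal confidence ellipses per group.
#'
#' @param object A `virosig_pcoa`.
#' @param groups Optional named vector of group labels per sample id.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.virosig_pcoa <- function(object, groups = NULL, ...) {
  df <- tidy(object)
  lab <- function(i) sprintf("PCo%d (%.1f%%)", i,
                             100 * object$explained_variance[i])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PCo1, y = .data$PCo2))
  if (!is.null(groups)) {
    df$group <- groups[df$sample_id]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PCo1, y = .data$PCo2,
                                          colour = .data$group)) +
      ggplot2::stat_ellipse(level = 0.95)
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}

#' Plot dual-modality signature calls
#'
#' Scatter of per-vOTU q-values in the VLP vs bulk datasets (-log10 scale),
#' coloured by signature status, with the significance threshold drawn on
#' both axes.
#'
#' @param object A `virosig_signatures`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.virosig_signatures <- function(object, ...) {
  df <- object$results |>
    dplyr::filter(.data$status != "not_tested")
  thr <- -log10(object$alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$q_vlp),
                                   y = -log10(.data$q_bulk),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      case_enriched = "#c0392b", control_enriched = "#2980b9",
      not_significant = "grey60")) +
    ggplot2::labs(x = "-log10 q (VLP)", y = "-log10 q (bulk)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of the cross-dataset AUC matrix
#'
#' @param auc_matrix Square matrix from [cross_dataset_auc()].
#' @return A ggplot object.
#' @export
plot_transfer_auc <- function(auc_matrix) {
  df <- tibble::as_tibble(auc_matrix, rownames = "train") |>
    tidyr::pivot_longer(-"train", names_to = "test", values_to = "auc")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$test, y = .data$train,
                                   fill = .data$auc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$auc))) +
    ggplot2::scale_fill_gradient(low = "white", high = "#c0392b",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "validated on", y = "trained on", fill = "AUC") +
    ggplot2::theme_minimal()
}
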