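# ggplot2 views of each result type: volcano for a DE fit, module
# expression by cell state, PCA scores, and the degree distribution with
# the hub threshold.

#' Volcano plot of a DE fit
#'
#' @param object An `rbp_dge` from [wald_test()].
#' @param lfc_min,alpha Thresholds drawn and used to colour selected
#'   genes.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rbp_dge
#' @export
autoplot.rbp_dge <- function(object, lfc_min = 1.5, alpha = 0.05, ...) {
  df <- object$table |>
    dplyr::mutate(selected = abs(.data$log2fc) >= lfc_min &
                    .data$padj <= alpha)
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$pvalue),
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = "selected",
                  title = sprintf("%s vs %s", object$contrast[1],
                                  object$contrast[2])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Module expression by cell state
#'
#' Box plots of pooled per-module expression (all genes x samples of a
#' group), one panel per module.
#'
#' @param assign Module assignment (`gene`, `module`).
#' @param expr Expression matrix.
#' @param samples Sample table (`sample`, `group`).
#' @return A ggplot object.
#' @export
plot_module_expression <- function(assign, expr, samples) {
  df <- as_tibble(expr, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "expr") |>
    dplyr::inner_join(assign, by = "gene") |>
    dplyr::inner_join(samples[, c("sample", "group")], by = "sample")
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$expr,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::facet_wrap(~module, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "log2 normalized expression") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' PCA score plot of samples
#'
#' @param struct Result of [sample_structure()].
#' @param samples Optional sample table to colour points by group.
#' @return A ggplot object.
#' @export
plot_pca <- function(struct, samples = NULL) {
  df <- struct$pca$scores
  if (!is.null(samples))
    df <- dplyr::inner_join(df, samples[, c("sample", "group")],
                            by = "sample")
  vr <- struct$pca$variance_ratio
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  p <- if (!is.null(samples))
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  else p + ggplot2::geom_point(size = 2)
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", 100 * vr[1]),
    y = sprintf("PC2 (%.1f%%)", 100 * vr[2])) +
    ggplot2::theme_minimal()
}

#' Degree distribution of the shortest-path network
#'
#' Histogram of union-network degrees with the hub threshold marked.
#'
#' @param hubs Hub table from [call_hubs()].
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(hubs) {
  thr <- attr(hubs, "degree_threshold")
  ggplot2::ggplot(hubs, ggplot2::aes(.data$degree)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = thr - 0.5, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "degree", y = "nodes",
                  subtitle = sprintf("hub threshold: degree >= %d", thr)) +
    ggplot2::theme_minimal()
}
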