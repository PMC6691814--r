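# broom-style accessors for the DE fit object.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a DE fit into its per-gene table
#'
#' @param x An `rbp_dge` object from [wald_test()].
#' @param ... Unused.
#' @return Tibble with columns `gene`, `base_mean`, `log2fc`, `se`,
#'   `stat`, `pvalue`, `padj`.
#' @method tidy rbp_dge
#' @export
tidy.rbp_dge <- function(x, ...) x$table

#' One-row summary of a DE fit
#'
#' @param x An `rbp_dge` object.
#' @param lfc_min,alpha Thresholds used for the significance count
#'   (defaults 1.5 and 0.05).
#' @param ... Unused.
#' @return One-row tibble: contrast groups, gene and sample counts, and
#'   the number of genes passing the thresholds.
#' @method glance rbp_dge
#' @export
glance.rbp_dge <- function(x, lfc_min = 1.5, alpha = 0.05, ...) {
  tibble(reference = x$contrast[1], test = x$contrast[2],
         n_genes = nrow(x$table),
         n_samples = sum(x$n_samples),
         n_de = length(select_de(x, lfc_min, alpha)),
         lfc_min = lfc_min, alpha = alpha)
}
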