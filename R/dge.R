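# Count filtering, median-of-ratios normalisation, shifted-log transform,
# method-of-moments NB dispersion, a Wald test for two-group differential
# expression with BH FDR control, and expression-pattern clustering of the
# DE genes.

DISPERSION_FLOOR <- 1e-8

#' Remove genes with uniformly low counts
#'
#' A gene is dropped iff its count is below `min_count` in *every* sample
#' (keeping any gene that reaches the threshold in at least one sample).
#'
#' @param counts Count matrix (genes x samples).
#' @param min_count Threshold, default 10.
#' @return The filtered count matrix; samples unchanged.
#' @export
filter_low_counts <- function(counts, min_count = 10) {
  validate_counts(counts)
  keep <- apply(counts, 1, function(x) any(x >= min_count))
  if (!any(keep)) warn("All genes removed by the low-count filter.")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of
#' `count / geometric mean across samples`, using only genes with strictly
#' positive counts in every sample.
#'
#' @param counts Count matrix.
#' @param pseudocount Optional pseudocount added to every cell before
#'   computing factors, for matrices with no all-positive gene. Default
#'   `NULL` (none).
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts, pseudocount = NULL) {
  m <- counts
  if (!is.null(pseudocount)) m <- m + pseudocount
  ref <- apply(m, 1, function(x) all(x > 0))
  if (!any(ref))
    abort(paste0("No gene has positive counts in every sample; ",
                 "call size_factors(counts, pseudocount = 1)."))
  logm <- log(m[ref, , drop = FALSE])
  loggeo <- rowMeans(logm)
  apply(exp(sweep(logm, 1, loggeo)), 2, median)
}

#' Shifted-log transform of normalized counts
#'
#' `log2(count / size_factor + pseudocount)`. A deliberate simplification of
#' the regularized-log transform: it preserves the sample- and gene-level
#' structure needed for PCA, correlation and clustering without per-gene
#' shrinkage.
#'
#' @param counts Count matrix.
#' @param factors Positive per-sample size factors (default: computed by
#'   [size_factors()]).
#' @param pseudocount Shift, default 1 (so a zero count maps to 0).
#' @return Real matrix with the dimensions and dimnames of `counts`.
#' @export
transform_log <- function(counts, factors = size_factors(counts),
                          pseudocount = 1) {
  if (any(factors <= 0)) abort("Size factors must be positive.")
  log2(sweep(counts, 2, factors, `/`) + pseudocount)
}

#' Method-of-moments NB dispersion per gene
#'
#' On normalized counts, pooling the within-group variance across groups:
#' `alpha_g = max((s2_g - m_g) / m_g^2, 1e-8)` with `m_g` the grand mean of
#' normalized counts and `s2_g` the pooled within-group sample variance.
#'
#' @param counts Count matrix.
#' @param samples Sample table (columns `sample`, `group`); every group
#'   needs >= 2 replicates.
#' @param factors Size factors (default computed).
#' @return Named numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(counts, samples,
                                factors = size_factors(counts)) {
  samples <- samples[match(colnames(counts), samples$sample), ]
  if (anyNA(samples$sample)) abort("Every count column needs a sample-table row.")
  if (any(table(samples$group) < 2)) abort("Every group needs >= 2 replicates.")
  norm <- sweep(counts, 2, factors, `/`)
  grand <- rowMeans(norm)
  grps <- split(seq_len(ncol(norm)), samples$group)
  ss <- Reduce(`+`, lapply(grps, function(ix) {
    gm <- rowMeans(norm[, ix, drop = FALSE])
    rowSums((norm[, ix, drop = FALSE] - gm)^2)
  }))
  s2 <- ss / (ncol(norm) - length(grps))
  pmax((s2 - grand) / grand^2, DISPERSION_FLOOR)
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Subsets the counts to the two groups of the contrast (the count matrix
#' of a comparison), normalizes by median-of-ratios, estimates per-gene NB
#' dispersion by method of moments, and tests
#' `log2fc = log2((m_test + c) / (m_ref + c))` (pseudocount `c = 0.5` on
#' normalized group means) with a delta-method standard error from the NB
#' variance of the group means, a two-sided normal p-value and
#' Benjamini-Hochberg adjustment across the tested genes.
#'
#' @param counts Count matrix.
#' @param samples Sample table (`sample`, `group`).
#' @param contrast Character vector `c(reference_group, test_group)`.
#' @param pseudocount Fold-change pseudocount, default 0.5.
#' @param moderate_dispersion Replace each gene-wise dispersion by the
#'   maximum of itself and the median dispersion across genes (default
#'   TRUE). With few replicates the raw method-of-moments estimate is
#'   noisy and underestimates for a sizable minority of genes, inflating
#'   Wald statistics; this conservative moderation restores type-I-error
#'   calibration at a negligible power cost.
#' @return An object of class `rbp_dge`; use [tidy()] for the per-gene
#'   table (gene, base_mean, log2fc, se, stat, pvalue, padj) and
#'   [glance()] for a one-row summary.
#' @export
wald_test <- function(counts, samples, contrast, pseudocount = 0.5,
                      moderate_dispersion = TRUE) {
  if (length(contrast) != 2) abort("`contrast` must be c(reference, test).")
  missing_grp <- setdiff(contrast, samples$group)
  if (length(missing_grp) > 0)
    abort(paste0("Group absent from sample table: ", missing_grp[1]))
  keep <- samples$sample[samples$group %in% contrast]
  sub <- counts[, colnames(counts) %in% keep, drop = FALSE]
  smp <- samples[match(colnames(sub), samples$sample), ]
  if (any(table(factor(smp$group, levels = contrast)) < 2))
    abort("Both contrast groups need >= 2 samples.")

  sf <- size_factors(sub, pseudocount = if (any(apply(sub, 1, min) > 0)) NULL else 0.5)
  norm <- sweep(sub, 2, sf, `/`)
  alpha <- estimate_dispersion(sub, smp, factors = sf)
  if (moderate_dispersion) alpha <- pmax(alpha, median(alpha))

  ref_ix <- which(smp$group == contrast[1])
  tst_ix <- which(smp$group == contrast[2])
  m_ref <- rowMeans(norm[, ref_ix, drop = FALSE])
  m_tst <- rowMeans(norm[, tst_ix, drop = FALSE])
  c0 <- pseudocount
  log2fc <- log2((m_tst + c0) / (m_ref + c0))

  # Var(mean of K_gs / s_s) with Var(K) = mu + alpha mu^2, mu_gs = s_s m_g
  var_mean <- function(m, ix) {
    sapply_rows <- outer(m, 1 / sf[ix]) + alpha * m^2
    rowSums(sapply_rows) / length(ix)^2
  }
  v_ref <- var_mean(m_ref, ref_ix)
  v_tst <- var_mean(m_tst, tst_ix)
  ln2 <- log(2)
  se <- sqrt(v_tst / ((m_tst + c0) * ln2)^2 + v_ref / ((m_ref + c0) * ln2)^2)
  stat <- ifelse(se > 0, log2fc / se, 0)
  pvalue <- ifelse(se > 0, 2 * pnorm(-abs(stat)), 1)
  padj <- p.adjust(pvalue, method = "BH")

  tbl <- tibble(gene = rownames(sub),
                base_mean = unname(rowMeans(norm)),
                log2fc = unname(log2fc), se = unname(se),
                stat = unname(stat), pvalue = unname(pvalue),
                padj = unname(padj))
  structure(list(table = tbl, contrast = contrast,
                 pseudocount = pseudocount, size_factors = sf,
                 n_samples = c(reference = length(ref_ix),
                               test = length(tst_ix))),
            class = "rbp_dge")
}

#' @export
print.rbp_dge <- function(x, ...) {
  cat(sprintf("Two-group NB Wald test: %s vs %s (%d genes, %d + %d samples)\n",
              x$contrast[1], x$contrast[2], nrow(x$table),
              x$n_samples[1], x$n_samples[2]))
  print(x$table, ...)
  invisible(x)
}

#' Select differentially expressed genes
#'
#' Genes with `|log2fc| >= lfc_min` and `padj <= alpha` (both boundaries
#' inclusive).
#'
#' @param table An `rbp_dge` fit or its tidy per-gene table.
#' @param lfc_min Absolute log2 fold-change threshold, default 1.5
#'   (the stem-vs-progenitor contrast in the source study used 1.2).
#' @param alpha FDR threshold, default 0.05.
#' @return Character vector of selected gene identifiers.
#' @export
select_de <- function(table, lfc_min = 1.5, alpha = 0.05) {
  if (inherits(table, "rbp_dge")) table <- table$table
  sel <- abs(table$log2fc) >= lfc_min & table$padj <= alpha
  table$gene[which(sel)]
}

#' Row-wise z-scores
#'
#' Centers and scales each row to mean 0 and sample standard deviation 1;
#' constant rows map to all zeros with a warning.
#'
#' @param m Real matrix with >= 2 columns.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  if (ncol(m) < 2) abort("z-scoring needs >= 2 values per row.")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  const <- s == 0 | is.na(s)
  if (any(const)) {
    warn(sprintf("%d constant row(s) z-scored to zero.", sum(const)))
    s[const] <- 1
  }
  out <- (m - mu) / s
  out[const, ] <- 0
  out
}

#' Cluster genes by expression pattern
#'
#' Agglomerative (average-linkage) clustering of z-scored rows under
#' Euclidean distance, with the tree cut to exactly `k` clusters. Labels
#' are renumbered by decreasing cluster size, ties broken by the smallest
#' gene identifier in the cluster.
#'
#' @param m Real matrix (genes x samples), e.g. log expression of DE genes.
#' @param k Number of clusters, `1 <= k <= nrow(m)`.
#' @return Tibble with columns `gene`, `cluster`.
#' @export
cluster_rows <- function(m, k) {
  if (k < 1) abort("`k` must be >= 1.")
  if (k > nrow(m)) abort("`k` exceeds the number of rows.")
  z <- suppressWarnings(zscore_rows(m))
  hc <- hclust(dist(z), method = "average")
  raw <- cutree(hc, k = k)
  tibble(gene = rownames(m), cluster = renumber_by_size(raw, rownames(m)))
}

# Renumber integer labels by decreasing group size; ties by the smallest
# member identifier.
renumber_by_size <- function(labels, ids) {
  info <- tibble(label = labels, id = ids) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(), first_id = min(.data$id), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$first_id)
  match(labels, info$label)
}
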