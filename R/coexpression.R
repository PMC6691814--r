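# Gene-gene Spearman correlation, module detection by correlation
# clustering, per-module cell-state contrasts (Wilcoxon rank-sum), RBP
# class composition, sample-level structure (PCA + sample correlation)
# and UpSet-style exclusive set intersections.

#' Pairwise Spearman correlation between genes
#'
#' Spearman rho with average-rank tie handling and a p-value from the
#' t-distribution approximation. Constant genes are flagged and given
#' rho = 0 against everything (1 on the diagonal).
#'
#' @param expr Real matrix, genes x samples (>= 3 samples); typically the
#'   log expression of the RBP genes.
#' @return A `corr_matrix` list: `entities` (gene ids), `rho` and `pval`
#'   (symmetric matrices), `constant` (flagged gene ids).
#' @export
gene_spearman <- function(expr) {
  if (ncol(expr) < 3) abort("Correlation needs >= 3 samples.")
  const <- apply(expr, 1, function(x) sd(x) == 0 || is.na(sd(x)))
  rho <- suppressWarnings(cor(t(expr), method = "spearman"))
  rho[const, ] <- 0
  rho[, const] <- 0
  diag(rho) <- 1
  if (any(const))
    warn(sprintf("%d constant gene(s) set to zero correlation.", sum(const)))
  n <- ncol(expr)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pval <- 2 * pt(-abs(tstat), df = n - 2)
  pval[abs(rho) >= 1] <- 0
  diag(pval) <- 0
  structure(list(entities = rownames(expr), rho = rho, pval = pval,
                 constant = rownames(expr)[const]),
            class = "corr_matrix")
}

#' Detect co-expression modules
#'
#' Agglomerative average-linkage clustering of genes under the distance
#' `1 - rho`, cut to exactly `k` modules. Modules are numbered by
#' decreasing size (ties by smallest gene identifier), matching the
#' convention of naming the largest module I.
#'
#' @param corr A `corr_matrix` from [gene_spearman()].
#' @param k Number of modules (>= 1, <= number of genes).
#' @return Tibble with columns `gene`, `module`; the cut height is attached
#'   as attribute `"cut_height"`.
#' @export
detect_modules <- function(corr, k) {
  if (k < 1) abort("`k` must be >= 1.")
  n <- length(corr$entities)
  if (k > n) abort("`k` exceeds the number of genes.")
  hc <- hclust(stats::as.dist(1 - corr$rho), method = "average")
  raw <- cutree(hc, k = k)
  height <- if (k == 1) max(hc$height) else if (k >= n) 0 else hc$height[n - k]
  out <- tibble(gene = corr$entities,
                module = renumber_by_size(raw, corr$entities))
  attr(out, "cut_height") <- height
  out
}

# Wilcoxon rank-sum p-value: exact two-sided when both samples are small
# and untied, otherwise normal approximation with tie correction.
wilcox_p <- function(x, y, exact_max = 20) {
  use_exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = !use_exact)$p.value)
}

#' Summarize module expression by cell state
#'
#' Per module and group, the median over all (gene, sample-in-group)
#' expression values, plus a two-sided Wilcoxon rank-sum p-value for every
#' group pair (exact for small untied samples, normal approximation with
#' tie correction otherwise).
#'
#' @param assign Module assignment tibble (`gene`, `module`).
#' @param expr Real expression matrix containing the assigned genes.
#' @param samples Sample table (`sample`, `group`), every group >= 2
#'   samples.
#' @return A `module_summary` list with tibbles `medians`
#'   (module, group, n, median_expr) and `tests`
#'   (module, group1, group2, pvalue).
#' @export
summarize_module <- function(assign, expr, samples) {
  samples <- samples[match(colnames(expr), samples$sample), ]
  if (any(table(samples$group) < 2)) abort("Every group needs >= 2 samples.")
  groups <- unique(samples$group)
  mods <- sort(unique(assign$module))
  pooled <- function(mod, grp) {
    g <- assign$gene[assign$module == mod]
    as.vector(expr[rownames(expr) %in% g,
                   samples$group == grp, drop = FALSE])
  }
  medians <- tidyr::expand_grid(module = mods, group = groups) |>
    dplyr::mutate(values = purrr::map2(.data$module, .data$group, pooled),
                  n = lengths(.data$values),
                  median_expr = purrr::map_dbl(.data$values, median)) |>
    dplyr::select(-"values")
  pairs <- if (length(groups) >= 2) combn(groups, 2, simplify = FALSE) else list()
  tests <- purrr::map_dfr(mods, function(mod) {
    purrr::map_dfr(pairs, function(pr) {
      tibble(module = mod, group1 = pr[1], group2 = pr[2],
             pvalue = wilcox_p(pooled(mod, pr[1]), pooled(mod, pr[2])))
    })
  })
  structure(list(medians = medians, tests = tests), class = "module_summary")
}

#' RBP class composition of modules
#'
#' Counts of genes per (module, RBP class); per-module counts sum to the
#' module size.
#'
#' @param assign Module (or cluster) assignment tibble (`gene`, `module`).
#' @param anno Gene annotation (`gene`, `is_rbp`, `rbp_class`).
#' @return Tibble with columns `module`, `rbp_class`, `n`.
#' @export
class_composition <- function(assign, anno) {
  missing_gene <- setdiff(assign$gene, anno$gene)
  if (length(missing_gene) > 0)
    abort(paste0("Gene without annotation: ", missing_gene[1]))
  assign |>
    dplyr::inner_join(anno, by = "gene") |>
    dplyr::count(.data$module, .data$rbp_class) |>
    dplyr::arrange(.data$module, dplyr::desc(.data$n), .data$rbp_class)
}

#' Sample-level structure: PCA and sample correlation
#'
#' PCA on gene-centered expression with samples as observations (scores
#' for the leading components, full variance-ratio spectrum) and the
#' Spearman correlation matrix between samples, with a deterministic
#' average-linkage leaf order for heat-map display.
#'
#' @param expr Real matrix, genes x samples (>= 3 samples).
#' @param n_components Number of score columns to report (default 3).
#' @return List with `pca` (list: `scores` tibble, `variance_ratio`) and
#'   `sample_corr` (`corr_matrix` over samples with attribute
#'   `"leaf_order"`).
#' @export
sample_structure <- function(expr, n_components = 3) {
  if (ncol(expr) < 3) abort("Sample structure needs >= 3 samples.")
  pc <- prcomp(t(expr), center = TRUE, scale. = FALSE)
  vr <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(sample = colnames(expr)), scores)

  rho <- cor(expr, method = "spearman")
  n_g <- nrow(expr)
  tstat <- rho * sqrt((n_g - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pval <- 2 * pt(-abs(tstat), df = n_g - 2)
  diag(pval) <- 0
  hc <- hclust(stats::as.dist(1 - rho), method = "average")
  sc <- structure(list(entities = colnames(expr), rho = rho, pval = pval,
                       constant = character(0)), class = "corr_matrix")
  attr(sc, "leaf_order") <- colnames(expr)[hc$order]
  list(pca = list(scores = scores, variance_ratio = vr), sample_corr = sc)
}

#' Exclusive set intersections (UpSet semantics)
#'
#' For named sets, the size of every exclusive membership region, keyed by
#' the membership bit pattern. Region sizes sum to the union size.
#'
#' @param sets Named list of >= 2 character vectors.
#' @return Tibble with one logical column per set, plus `combination`
#'   (ampersand-joined member set names), `degree` and `size`; only
#'   non-empty regions are returned, sorted by decreasing size.
#' @export
set_intersections <- function(sets) {
  if (length(sets) < 2) abort("Need at least 2 sets.")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    abort("Sets must be named.")
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  memb <- matrix(memb, nrow = length(universe),
                 dimnames = list(universe, names(sets)))
  pattern <- apply(memb, 1, function(r) paste(names(sets)[r], collapse = "&"))
  out <- as_tibble(memb) |>
    dplyr::mutate(combination = unname(pattern),
                  degree = rowSums(memb)) |>
    dplyr::count(dplyr::across(dplyr::everything()), name = "size") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$combination)
  out
}
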