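# Readers and writers for the tabular and graph artifacts shared by every
# stage: count matrices, sample tables, gene annotations, STRING-dialect
# edge lists and gene<->protein ID maps. All identifier conventions are
# owned here.

#' Validate a count matrix
#'
#' Checks the invariants every count matrix must satisfy: named rows (genes)
#' and columns (samples) without duplicates, at least two samples, and
#' non-negative integral entries.
#'
#' @param counts Integer matrix, genes in rows, samples in columns.
#' @return The validated matrix (invisibly storage-mode integer).
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts)) abort("`counts` must be a matrix (genes x samples).")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("`counts` must have gene rownames and sample colnames.")
  dup_g <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup_g) > 0)
    abort(paste0("Duplicate gene identifier(s): ", paste(unique(dup_g), collapse = ", ")))
  dup_s <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup_s) > 0)
    abort(paste0("Duplicate sample identifier(s): ", paste(unique(dup_s), collapse = ", ")))
  if (ncol(counts) < 2) abort("A count matrix needs at least 2 samples.")
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Non-integer or negative count for gene '%s', sample '%s'.",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  storage.mode(counts) <- "integer"
  invisible(counts)
}

#' Read a gene x sample count matrix from TSV
#'
#' The file must have a header row of sample identifiers and gene
#' identifiers in the first column. Row and column order are preserved.
#'
#' @param path Path to a tab-separated file.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  df <- suppressMessages(readr::read_tsv(path, show_col_types = FALSE))
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("Count matrix contains non-numeric entries.")
  rownames(m) <- genes
  validate_counts(m)
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix to TSV
#'
#' @param counts Validated count matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  df <- tibble(gene = rownames(counts))
  df <- dplyr::bind_cols(df, as_tibble(counts))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a sample table (sample, group)
#'
#' @param path TSV with columns `sample` and `group` (cell-state label such
#'   as HSC/CMP/GMP/Mono/LSC/Blast); extra columns are kept.
#' @return Tibble with character `sample` and `group`.
#' @export
read_sample_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols())
  if (!all(c("sample", "group") %in% names(df)))
    abort("Sample table needs columns `sample` and `group`.")
  if (anyDuplicated(df$sample))
    abort("Duplicate sample identifiers in sample table.")
  dplyr::mutate(df, sample = as.character(.data$sample),
                group = as.character(.data$group))
}

#' Read a gene annotation table (gene, is_rbp, rbp_class)
#'
#' Enforces the closed class vocabulary and the rule that `rbp_class` is
#' `"none"` exactly for non-RBP genes.
#'
#' @param path TSV with columns `gene`, `is_rbp`, `rbp_class`.
#' @return Tibble.
#' @export
read_gene_annotation <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols())
  validate_annotation(df)
}

#' @rdname read_gene_annotation
#' @param anno A data frame to validate in place of reading a file.
#' @export
validate_annotation <- function(anno) {
  if (!all(c("gene", "is_rbp", "rbp_class") %in% names(anno)))
    abort("Annotation needs columns `gene`, `is_rbp`, `rbp_class`.")
  anno <- dplyr::mutate(as_tibble(anno), is_rbp = as.logical(.data$is_rbp))
  bad_class <- setdiff(unique(anno$rbp_class), c(RBP_CLASSES, "none"))
  if (length(bad_class) > 0)
    abort(paste0("Unknown rbp_class value(s): ", paste(bad_class, collapse = ", ")))
  mism <- anno$gene[(anno$rbp_class == "none") != (!anno$is_rbp)]
  if (length(mism) > 0)
    abort(paste0("rbp_class must be 'none' iff is_rbp is FALSE; violated for: ",
                 paste(head(mism, 5), collapse = ", ")))
  if (anyDuplicated(anno$gene)) abort("Duplicate gene in annotation.")
  anno
}

#' Read a STRING-dialect protein interaction edge list
#'
#' Accepts space- or tab-delimited files with columns
#' `protein1 protein2 combined_score` (the header is auto-detected from a
#' non-numeric third field). Edges are canonicalized to undirected form
#' (`node_a <= node_b` lexicographically), duplicates collapse to the
#' maximum score, and self-edges are dropped with a message.
#'
#' @param path Path to the edge-list file.
#' @return Tibble with columns `node_a`, `node_b`, `combined_score`.
#' @export
read_edge_list <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("Empty edge list file.")
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    abort(sprintf("Edge list line %d has fewer than 3 columns.", which(nf < 3)[1]))
  # header detection: non-numeric third field on the first line
  if (is.na(suppressWarnings(as.numeric(fields[[1]][3])))) fields <- fields[-1]
  if (length(fields) == 0) abort("Edge list has a header but no data rows.")
  a <- vapply(fields, `[[`, character(1), 1)
  b <- vapply(fields, `[[`, character(1), 2)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  if (anyNA(s)) abort("Non-numeric combined_score in edge list.")
  canonicalize_edges(tibble(node_a = a, node_b = b, combined_score = s))
}

#' Canonicalize an undirected edge list
#'
#' @param edges Data frame with `node_a`, `node_b`, `combined_score`.
#' @return Tibble of canonical edges (`node_a <= node_b`, self-edges
#'   removed, duplicates collapsed keeping the maximum score).
#' @export
canonicalize_edges <- function(edges) {
  edges <- as_tibble(edges)
  s <- edges$combined_score
  if (any(s < 0 | s > 1000))
    abort(sprintf("combined_score out of [0, 1000]: %s", s[s < 0 | s > 1000][1]))
  self <- edges$node_a == edges$node_b
  if (any(self)) inform(sprintf("Dropped %d self-edge(s).", sum(self)))
  edges <- edges[!self, , drop = FALSE]
  swap <- edges$node_a > edges$node_b
  tmp <- edges$node_a[swap]
  edges$node_a[swap] <- edges$node_b[swap]
  edges$node_b[swap] <- tmp
  edges |>
    dplyr::group_by(.data$node_a, .data$node_b) |>
    dplyr::summarise(combined_score = max(.data$combined_score), .groups = "drop") |>
    dplyr::arrange(.data$node_a, .data$node_b)
}

#' Write an edge list in STRING dialect
#'
#' @param edges Canonical edge tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  out <- tibble(protein1 = edges$node_a, protein2 = edges$node_b,
                combined_score = edges$combined_score)
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a gene to protein identifier map
#'
#' Two-column TSV (`gene`, `protein`); many-to-many mappings are allowed and
#' duplicate rows are collapsed. A message reports how many genes map to one
#' vs several proteins. Genes absent from the map are treated as unmapped by
#' downstream stages, never as an error.
#'
#' @param path Path to TSV.
#' @return Tibble with columns `gene`, `protein`.
#' @export
read_id_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0) abort("Empty ID map file.")
  if (ncol(df) < 2) abort("ID map needs two columns (gene, protein).")
  names(df)[1:2] <- c("gene", "protein")
  df <- dplyr::distinct(df[, c("gene", "protein")])
  per_gene <- dplyr::count(df, .data$gene)
  inform(sprintf("ID map: %d genes with 1 protein, %d genes with >1 protein.",
                 sum(per_gene$n == 1), sum(per_gene$n > 1)))
  df
}

#' Write a result table to TSV deterministically
#'
#' Floating-point columns are printed at 6 significant digits and rows are
#' sorted by the first (primary key) column so repeated runs are
#' byte-identical.
#'
#' @param rows Data frame with a defined column schema.
#' @param path Output path.
#' @param sort Sort rows by the first column (default TRUE).
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, sort = TRUE) {
  rows <- as_tibble(rows)
  if (sort && ncol(rows) > 0 && nrow(rows) > 1)
    rows <- dplyr::arrange(rows, dplyr::across(1))
  rows <- dplyr::mutate(rows, dplyr::across(
    dplyr::where(is.double), ~ signif(.x, 6)))
  readr::write_tsv(rows, path)
  invisible(path)
}
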