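# DE-constrained shortest-path analysis over a confidence-filtered PPI:
# graph construction from a STRING-dialect edge list, DE/RBP annotation via
# the gene<->protein map, all unweighted shortest paths between RBP nodes,
# significance filtering of whole paths, union network construction,
# degree-percentile hub calling, hub class composition and the IQR-based
# low/high hub expression split.

#' Build a confidence-filtered PPI graph
#'
#' Keeps edges with `combined_score >= min_score` (STRING's 0-1000
#' convention; 500 is "medium-high" confidence) and drops nodes left
#' isolated. The result is a simple undirected graph.
#'
#' @param edges Canonical edge tibble (`node_a`, `node_b`,
#'   `combined_score`), e.g. from [read_edge_list()] or [simulate_ppi()].
#' @param min_score Minimum retained confidence score, default 500.
#' @return An undirected `igraph` graph with edge attribute
#'   `combined_score`.
#' @export
build_graph <- function(edges, min_score = 500) {
  edges <- suppressMessages(canonicalize_edges(edges))
  keep <- edges[edges$combined_score >= min_score, , drop = FALSE]
  if (nrow(keep) == 0)
    abort(sprintf(
      "No edge passes the score filter (min_score = %s; %d edges, max score %s).",
      min_score, nrow(edges), if (nrow(edges)) max(edges$combined_score) else NA))
  igraph::graph_from_data_frame(keep, directed = FALSE)
}

#' Annotate a PPI graph with DE results and RBP status
#'
#' Every protein inherits the differential-expression record (log2fc, padj)
#' and RBP flag of its mapped gene through the gene-protein ID map. A gene
#' mapping to several proteins stamps all of them; when several genes map
#' to one protein the smallest adjusted p wins (conservative for path
#' retention) and the conflict is reported. Proteins with no mapped gene or
#' no DE record are marked non-significant (`padj = NA`), so they can never
#' survive path filtering.
#'
#' @param graph PPI graph from [build_graph()].
#' @param idmap Gene-protein map tibble (`gene`, `protein`).
#' @param de An `rbp_dge` fit or tidy DE table (`gene`, `log2fc`, `padj`).
#' @param anno Gene annotation (`gene`, `is_rbp`, `rbp_class`).
#' @return The graph with vertex attributes `gene`, `is_rbp`, `rbp_class`,
#'   `log2fc`, `padj`.
#' @export
annotate_graph <- function(graph, idmap, de, anno) {
  if (inherits(de, "rbp_dge")) de <- de$table
  rec <- idmap |>
    dplyr::inner_join(de[, c("gene", "log2fc", "padj")], by = "gene") |>
    dplyr::left_join(anno[, c("gene", "is_rbp", "rbp_class")], by = "gene")
  conflicts <- sum(duplicated(rec$protein))
  if (conflicts > 0)
    inform(sprintf(
      "%d protein(s) mapped by several genes; keeping the smallest padj.",
      conflicts))
  rec <- rec |>
    dplyr::arrange(.data$protein, .data$padj) |>
    dplyr::distinct(.data$protein, .keep_all = TRUE)
  nodes <- igraph::V(graph)$name
  ix <- match(nodes, rec$protein)
  graph <- igraph::set_vertex_attr(graph, "gene", value = rec$gene[ix])
  graph <- igraph::set_vertex_attr(graph, "is_rbp",
                                   value = !is.na(ix) & rec$is_rbp[ix] %in% TRUE)
  graph <- igraph::set_vertex_attr(graph, "rbp_class",
    value = ifelse(is.na(ix) | is.na(rec$rbp_class[ix]), "none",
                   rec$rbp_class[ix]))
  graph <- igraph::set_vertex_attr(graph, "log2fc", value = rec$log2fc[ix])
  graph <- igraph::set_vertex_attr(graph, "padj", value = rec$padj[ix])
  inform(sprintf(
    "Annotated graph: %d nodes (%d with DE record, %d RBP, %d unmapped).",
    length(nodes), sum(!is.na(ix)), sum(igraph::V(graph)$is_rbp),
    sum(is.na(ix))))
  graph
}

#' RBP nodes of an annotated graph
#'
#' @param graph Annotated PPI graph.
#' @return Character vector of protein identifiers flagged as RBPs.
#' @export
rbp_nodes <- function(graph) {
  igraph::V(graph)$name[igraph::V(graph)$is_rbp %in% TRUE]
}

#' All unweighted shortest paths between RBP endpoint pairs
#'
#' For every unordered pair of endpoints in the same connected component,
#' every hop-count shortest path in the full graph (edges unweighted,
#' whatever their confidence score), each emitted once in canonical
#' direction (lexicographically smaller endpoint first) and truncated at
#' `max_paths_per_pair` with the number of truncated pairs reported.
#'
#' @param graph PPI graph (annotation not required).
#' @param endpoints Character vector of >= 2 node names (the RBP nodes).
#' @param max_paths_per_pair Per-pair cap on emitted paths (default 100;
#'   use `Inf` for exhaustive enumeration on small graphs).
#' @return A `path_set`: list of character node sequences, with attribute
#'   `"truncated_pairs"`.
#' @export
shortest_path_set <- function(graph, endpoints, max_paths_per_pair = 100) {
  endpoints <- sort(unique(endpoints))
  missing_ep <- setdiff(endpoints, igraph::V(graph)$name)
  if (length(missing_ep) > 0) {
    inform(sprintf("%d endpoint(s) absent from the graph; ignored.",
                   length(missing_ep)))
    endpoints <- setdiff(endpoints, missing_ep)
  }
  if (length(endpoints) < 2) abort("Need >= 2 endpoints present in the graph.")
  paths <- list()
  truncated <- 0L
  for (i in seq_len(length(endpoints) - 1)) {
    from <- endpoints[i]
    to <- endpoints[(i + 1):length(endpoints)]
    res <- suppressWarnings(
      igraph::all_shortest_paths(graph, from = from, to = to))$res
    if (length(res) == 0) next
    seqs <- lapply(res, function(v) igraph::V(graph)$name[as.integer(v)])
    tgt <- vapply(seqs, function(p) p[length(p)], character(1))
    for (pieces in split(seqs, tgt)) {
      if (length(pieces) > max_paths_per_pair) {
        truncated <- truncated + 1L
        pieces <- pieces[seq_len(max_paths_per_pair)]
      }
      paths <- c(paths, pieces)
    }
  }
  if (truncated > 0)
    inform(sprintf("Truncated paths for %d endpoint pair(s).", truncated))
  structure(paths, class = "path_set", truncated_pairs = truncated)
}

#' Keep only paths whose every node is differentially expressed
#'
#' Retains exactly the paths (endpoints and intermediates alike, RBP or
#' not) in which every node's adjusted p-value is `<= alpha`. Nodes
#' without a DE record never pass.
#'
#' @param paths A `path_set`.
#' @param graph The annotated graph the paths were computed on.
#' @param alpha Adjusted-p threshold, default 0.05.
#' @return The filtered `path_set`.
#' @export
filter_paths <- function(paths, graph, alpha = 0.05) {
  padj <- setNames(igraph::V(graph)$padj, igraph::V(graph)$name)
  keep <- vapply(paths, function(p) {
    pv <- padj[p]
    all(!is.na(pv) & pv <= alpha)
  }, logical(1))
  structure(unclass(paths)[keep], class = "path_set",
            truncated_pairs = attr(paths, "truncated_pairs"))
}

#' Union network of retained shortest paths
#'
#' Nodes are the union of path nodes; edges the union of consecutive path
#' pairs (stored once); degrees are computed on this union graph.
#'
#' @param paths A `path_set` (typically after [filter_paths()]).
#' @param graph Optional source graph; when given, its vertex annotations
#'   are carried onto the union network's node table.
#' @return An `sp_network` list: `graph` (igraph), `nodes` tibble
#'   (node, degree and, if available, gene/is_rbp/rbp_class/log2fc/padj),
#'   `n_paths`.
#' @export
union_network <- function(paths, graph = NULL) {
  if (length(paths) == 0) {
    warn("Empty path set; returning an empty network.")
    return(structure(list(graph = igraph::make_empty_graph(directed = FALSE),
                          nodes = tibble(node = character(), degree = integer()),
                          n_paths = 0L), class = "sp_network"))
  }
  edges <- purrr::map_dfr(paths, function(p) {
    if (length(p) < 2) return(tibble(node_a = character(), node_b = character()))
    tibble(node_a = p[-length(p)], node_b = p[-1])
  })
  swap <- edges$node_a > edges$node_b
  tmp <- edges$node_a[swap]
  edges$node_a[swap] <- edges$node_b[swap]
  edges$node_b[swap] <- tmp
  edges <- dplyr::distinct(edges)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = sort(unique(unlist(paths))))
  deg <- igraph::degree(g)
  nodes <- tibble(node = names(deg), degree = as.integer(deg))
  if (!is.null(graph)) {
    ix <- match(nodes$node, igraph::V(graph)$name)
    for (a in intersect(c("gene", "is_rbp", "rbp_class", "log2fc", "padj"),
                        igraph::vertex_attr_names(graph)))
      nodes[[a]] <- igraph::vertex_attr(graph, a)[ix]
  }
  structure(list(graph = g, nodes = dplyr::arrange(nodes, .data$node),
                 n_paths = length(paths)), class = "sp_network")
}

#' @export
print.sp_network <- function(x, ...) {
  cat(sprintf("Shortest-path union network: %d nodes, %d edges from %d paths\n",
              nrow(x$nodes), igraph::ecount(x$graph), x$n_paths))
  invisible(x)
}

#' Call hub nodes by degree percentile
#'
#' The hub threshold is the nearest-rank percentile of the degree multiset
#' (the value at index `ceiling(p/100 * n)` of the ascending sorted
#' degrees); every node with degree at or above it -- including ties -- is
#' a hub. The default keeps the top 10 percentile of degree values.
#'
#' @param network An `sp_network` from [union_network()].
#' @param percentile Degree percentile defining hubs, default 90.
#' @return Tibble (`node`, `degree`, `is_hub`, plus carried annotations),
#'   sorted by decreasing degree, with attribute `"degree_threshold"`.
#' @export
call_hubs <- function(network, percentile = 90) {
  nodes <- network$nodes
  if (nrow(nodes) == 0) abort("Cannot call hubs on an empty network.")
  d <- sort(nodes$degree)
  thr <- d[ceiling(percentile / 100 * length(d))]
  out <- nodes |>
    dplyr::mutate(is_hub = .data$degree >= thr) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$node)
  attr(out, "degree_threshold") <- thr
  out
}

#' RBP class composition of hub nodes
#'
#' Counts hub nodes per RBP class (plus a `none` row for non-RBP hubs) and
#' the percentage each class contributes among RBP hubs.
#'
#' @param hubs Hub table from [call_hubs()] with a `gene` column (i.e. the
#'   union network was built from an annotated graph).
#' @param anno Gene annotation (`gene`, `is_rbp`, `rbp_class`).
#' @return Tibble (`rbp_class`, `n`, `pct_of_rbp_hubs`).
#' @export
hub_composition <- function(hubs, anno) {
  if (!"gene" %in% names(hubs))
    abort("`hubs` needs a `gene` column; build the network from an annotated graph.")
  h <- hubs[hubs$is_hub, , drop = FALSE] |>
    dplyr::left_join(anno[, c("gene", "rbp_class")], by = "gene",
                     suffix = c(".net", "")) |>
    dplyr::mutate(rbp_class = dplyr::coalesce(.data$rbp_class, "none"))
  comp <- dplyr::count(h, .data$rbp_class)
  n_rbp_hubs <- sum(comp$n[comp$rbp_class != "none"])
  if (n_rbp_hubs == 0) warn("No RBP among the hub nodes.")
  comp |>
    dplyr::mutate(pct_of_rbp_hubs = ifelse(
      .data$rbp_class == "none", NA_real_,
      100 * .data$n / max(n_rbp_hubs, 1L))) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$rbp_class)
}

#' Split hub genes into low/high expression groups by IQR
#'
#' Per hub gene, the mean expression over the contrast's samples; genes at
#' or below the first quartile of these means are `low`, at or above the
#' third quartile `high`, otherwise `none` (quartiles by linear
#' interpolation, boundaries inclusive). Each assigned gene also gets a
#' two-sided Wilcoxon rank-sum p-value comparing its expression between
#' the two contrast groups, flagged when `p < 0.05`.
#'
#' @param hubs Hub-table rows to split (e.g. the hubs of one hub cluster),
#'   with a `gene` column.
#' @param expr Real expression matrix containing the hub genes.
#' @param samples Sample table (`sample`, `group`).
#' @param contrast Character vector `c(group1, group2)`.
#' @return The hub rows with `mean_expr`, `expression_group`, `wilcox_p`
#'   and `significant` columns added.
#' @export
split_hubs_by_expression <- function(hubs, expr, samples, contrast) {
  samples <- samples[match(colnames(expr), samples$sample), ]
  in_contrast <- samples$group %in% contrast
  h <- hubs[!is.na(hubs$gene) & hubs$gene %in% rownames(expr), , drop = FALSE]
  if (nrow(h) == 0) abort("No hub gene present in the expression matrix.")
  means <- rowMeans(expr[h$gene, in_contrast, drop = FALSE])
  q <- quantile(means, c(0.25, 0.75), type = 7, names = FALSE)
  grp <- dplyr::case_when(
    means <= q[1] ~ "low",
    means >= q[2] ~ "high",
    .default = "none")
  if (q[1] == q[2]) {
    warn("All hub means equal; no low/high assignment possible.")
    grp[] <- "none"
  }
  pvals <- vapply(h$gene, function(g) {
    x <- expr[g, samples$group == contrast[1]]
    y <- expr[g, samples$group == contrast[2]]
    wilcox_p(x, y)
  }, double(1))
  h |>
    dplyr::mutate(mean_expr = unname(means),
                  expression_group = grp,
                  wilcox_p = ifelse(grp == "none", NA_real_, unname(pvals)),
                  significant = !is.na(.data$wilcox_p) & .data$wilcox_p < 0.05)
}
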