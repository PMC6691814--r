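# Independent oracles used across the suite. These deliberately avoid the
# code paths (and where possible the library calls) they are checking.

# Benjamini-Hochberg step-up, written out as the textbook procedure:
# sort p ascending, adj_(i) = min_{j >= i} m * p_(j) / j, capped at 1,
# mapped back to the original order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    running_min <- min(running_min, m * sorted[i] / i)
    adj[i] <- min(running_min, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Spearman as rank-then-Pearson, with explicit average ranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exhaustive simple-path enumeration by depth-first search over an
# adjacency list; returns every simple path from `from` to `to`.
all_simple_paths_oracle <- function(adj, from, to) {
  paths <- list()
  walk <- function(path) {
    tail_node <- path[length(path)]
    if (tail_node == to) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (nb in adj[[tail_node]]) {
      if (!(nb %in% path)) walk(c(path, nb))
    }
  }
  walk(from)
  paths
}

# Oracle for the shortest-path -> significance-filter -> union chain:
# for every unordered endpoint pair enumerate all simple paths, keep the
# minimum-length ones (the shortest paths of the full graph), then those
# whose nodes are all significant, and assemble the union network.
sp_chain_oracle <- function(edges, endpoints, padj, alpha = 0.05) {
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  adj <- setNames(lapply(nodes, function(n) {
    sort(c(edges$node_b[edges$node_a == n], edges$node_a[edges$node_b == n]))
  }), nodes)
  kept <- list()
  eps <- sort(intersect(endpoints, nodes))
  if (length(eps) >= 2) {
    for (i in seq_len(length(eps) - 1)) {
      for (j in (i + 1):length(eps)) {
        ps <- all_simple_paths_oracle(adj, eps[i], eps[j])
        if (length(ps) == 0) next
        lens <- lengths(ps)
        ps <- ps[lens == min(lens)]
        ok <- vapply(ps, function(p) {
          pv <- padj[p]
          all(!is.na(pv) & pv <= alpha)
        }, logical(1))
        kept <- c(kept, ps[ok])
      }
    }
  }
  if (length(kept) == 0)
    return(list(nodes = character(), edges = character(), degrees = integer()))
  uedges <- unique(unlist(lapply(kept, function(p) {
    a <- p[-length(p)]; b <- p[-1]
    paste(pmin(a, b), pmax(a, b), sep = "|")
  })))
  unodes <- sort(unique(unlist(kept)))
  deg <- setNames(integer(length(unodes)), unodes)
  for (e in uedges) {
    ab <- strsplit(e, "|", fixed = TRUE)[[1]]
    deg[ab] <- deg[ab] + 1L
  }
  list(nodes = unodes, edges = sort(uedges), degrees = deg)
}

# Shared fixture: the five-node worked example used in the network tests
# (square A-B-C, A-D-C with a pendant C-E) and its per-gene significance.
micro_graph <- function() {
  edges <- tibble::tibble(
    node_a = c("A", "B", "A", "C", "C"),
    node_b = c("B", "C", "D", "D", "E"),
    combined_score = c(900, 900, 900, 900, 900))
  padj <- c(A = 0.01, B = 0.2, C = 0.01, D = 0.03, E = 0.02)
  list(edges = edges, padj = padj)
}

# Annotate a graph's vertices directly with padj/is_rbp values, bypassing
# the idmap machinery, for small hand-built examples.
annotate_directly <- function(graph, padj, rbp = names(padj)) {
  nm <- igraph::V(graph)$name
  graph <- igraph::set_vertex_attr(graph, "padj", value = unname(padj[nm]))
  graph <- igraph::set_vertex_attr(graph, "gene", value = nm)
  igraph::set_vertex_attr(graph, "is_rbp", value = nm %in% rbp)
}
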