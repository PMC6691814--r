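# PPI graph construction, annotation, shortest paths, path filtering,
# union network, hub calling and the hub expression split.

test_that("graph construction keeps scores >= threshold and drops isolates", {
  e <- tibble::tibble(node_a = c("P1", "P2", "P4"),
                      node_b = c("P2", "P3", "P5"),
                      combined_score = c(500, 499, 1000))
  g <- build_graph(e, 500)
  expect_setequal(igraph::V(g)$name, c("P1", "P2", "P4", "P5"))
  expect_equal(igraph::ecount(g), 2)
  expect_false("P3" %in% igraph::V(g)$name)

  all_high <- tibble::tibble(node_a = "A", node_b = "B",
                             combined_score = 1000)
  expect_equal(igraph::ecount(build_graph(all_high)), 1)
  expect_error(build_graph(e, 1001), "No edge passes")
})

test_that("annotation propagates DE records through many-to-many maps", {
  e <- tibble::tibble(node_a = c("P1", "P2", "P9"),
                      node_b = c("P2", "P9", "P3"),
                      combined_score = 800)
  g <- build_graph(e)
  idmap <- tibble::tibble(gene = c("G1", "G1", "G2", "G3"),
                          protein = c("P1", "P2", "P3", "P3"))
  de <- tibble::tibble(gene = c("G1", "G2", "G3"),
                       log2fc = c(2, 1, -1),
                       padj = c(0.01, 0.2, 0.001))
  anno <- tibble::tibble(gene = c("G1", "G2", "G3"),
                         is_rbp = c(TRUE, FALSE, FALSE),
                         rbp_class = c("mRBP", "none", "none"))
  ann <- suppressMessages(annotate_graph(g, idmap, de, anno))
  padj <- setNames(igraph::V(ann)$padj, igraph::V(ann)$name)
  expect_equal(padj[["P1"]], 0.01)         # gene stamps all its proteins
  expect_equal(padj[["P2"]], 0.01)
  expect_equal(padj[["P3"]], 0.001)        # smaller padj wins the conflict
  expect_true(is.na(padj[["P9"]]))         # unmapped -> non-significant
  expect_setequal(rbp_nodes(ann), c("P1", "P2"))
})

test_that("the five-node worked example reproduces exactly", {
  mg <- micro_graph()
  g <- build_graph(mg$edges, 500)
  g <- annotate_directly(g, mg$padj, rbp = c("A", "E"))

  paths <- shortest_path_set(g, c("A", "E"))
  expect_equal(length(paths), 2)
  expect_setequal(vapply(paths, paste, "", collapse = "-"),
                  c("A-B-C-E", "A-D-C-E"))

  kept <- filter_paths(paths, g, 0.05)
  expect_equal(length(kept), 1)
  expect_equal(kept[[1]], c("A", "D", "C", "E"))

  net <- union_network(kept, g)
  deg <- setNames(net$nodes$degree, net$nodes$node)
  expect_equal(deg, c(A = 1L, C = 2L, D = 2L, E = 1L))
  expect_equal(igraph::ecount(net$graph), 3)
  expect_equal(sum(deg), 2 * igraph::ecount(net$graph))

  hubs <- call_hubs(net, 90)
  expect_setequal(hubs$node[hubs$is_hub], c("C", "D"))
})

test_that("path enumeration handles adjacent and disconnected endpoints", {
  e <- tibble::tibble(node_a = c("A", "C"), node_b = c("B", "D"),
                      combined_score = 900)
  g <- build_graph(e)
  adj <- shortest_path_set(g, c("A", "B"))
  expect_equal(length(adj), 1)
  expect_equal(adj[[1]], c("A", "B"))
  both <- shortest_path_set(g, c("A", "B", "C"))  # A-C disconnected
  expect_equal(length(both), 1)

  # alpha = 0 removes everything; alpha = 1 keeps everything
  g2 <- annotate_directly(g, c(A = 0.01, B = 0.01, C = 0.5, D = 0.5))
  expect_equal(length(filter_paths(adj, g2, 0)), 0)
  expect_equal(length(filter_paths(adj, g2, 1)), 1)
})

test_that("path caps truncate per pair with a message", {
  # two parallel 2-hop routes between A and C
  e <- tibble::tibble(node_a = c("A", "A", "B1", "B2"),
                      node_b = c("B1", "B2", "C", "C"),
                      combined_score = 900)
  g <- build_graph(e)
  full <- shortest_path_set(g, c("A", "C"), max_paths_per_pair = Inf)
  expect_equal(length(full), 2)
  expect_message(
    capped <- shortest_path_set(g, c("A", "C"), max_paths_per_pair = 1),
    "Truncated")
  expect_equal(length(capped), 1)
  expect_equal(attr(capped, "truncated_pairs"), 1L)
})

test_that("shortest-path chain equals the exhaustive simple-path oracle", {
  set.seed(77)
  for (rep in 1:200) {
    n <- sample(5:12, 1)
    nodes <- sprintf("N%02d", 1:n)
    prob <- runif(1, 0.2, 0.5)
    pairs <- t(combn(nodes, 2))
    sel <- runif(nrow(pairs)) < prob
    if (!any(sel)) next
    edges <- tibble::tibble(node_a = pairs[sel, 1], node_b = pairs[sel, 2],
                            combined_score = 900)
    padj <- setNames(runif(n, 0, 0.15), nodes)
    endpoints <- sample(nodes, sample(2:4, 1))

    g <- build_graph(edges, 500)
    g <- annotate_directly(g, padj)
    eps <- intersect(endpoints, igraph::V(g)$name)
    if (length(eps) < 2) next
    paths <- shortest_path_set(g, eps, max_paths_per_pair = Inf)
    kept <- filter_paths(paths, g, 0.05)
    net <- suppressWarnings(union_network(kept, g))

    oracle <- sp_chain_oracle(edges, eps, padj, 0.05)
    expect_identical(sort(net$nodes$node), oracle$nodes)
    if (length(oracle$nodes) > 0) {
      el <- igraph::as_edgelist(net$graph)
      got_edges <- sort(paste(pmin(el[, 1], el[, 2]),
                              pmax(el[, 1], el[, 2]), sep = "|"))
      expect_identical(got_edges, oracle$edges)
      expect_identical(setNames(net$nodes$degree, net$nodes$node)[oracle$nodes],
                       oracle$degrees)
    }
  }
})

test_that("union network is always a subgraph of the filtered PPI", {
  set.seed(5)
  genes <- sim_gene_ids(150)
  ppi <- simulate_ppi(genes, genes[1:40], n_hubs = 2, d_min = 8, seed = 5)
  g <- build_graph(ppi$edges, 500)
  padj <- setNames(runif(igraph::vcount(g), 0, 0.1), igraph::V(g)$name)
  g <- annotate_directly(g, padj, rbp = names(padj)[1:30])
  paths <- shortest_path_set(g, rbp_nodes(g))
  net <- suppressWarnings(union_network(filter_paths(paths, g), g))
  expect_true(all(net$nodes$node %in% igraph::V(g)$name))
  el <- igraph::as_edgelist(net$graph)
  expect_true(all(apply(el, 1, function(ab) igraph::are_adjacent(g, ab[1], ab[2]))))
  expect_equal(sum(net$nodes$degree), 2 * igraph::ecount(net$graph))
})

test_that("raising alpha grows the path set; raising min_score shrinks the graph", {
  set.seed(6)
  genes <- sim_gene_ids(80)
  ppi <- simulate_ppi(genes, genes[1:25], n_hubs = 1, d_min = 6,
                      frac_below_500 = 0.3, seed = 6)
  g_loose <- build_graph(ppi$edges, 400)
  g_tight <- build_graph(ppi$edges, 700)
  expect_lte(igraph::ecount(g_tight), igraph::ecount(g_loose))
  expect_lte(igraph::vcount(g_tight), igraph::vcount(g_loose))

  padj <- setNames(runif(igraph::vcount(g_loose), 0, 0.2),
                   igraph::V(g_loose)$name)
  g_loose <- annotate_directly(g_loose, padj, rbp = names(padj)[1:15])
  paths <- shortest_path_set(g_loose, rbp_nodes(g_loose))
  n_strict <- length(filter_paths(paths, g_loose, 0.02))
  n_loose <- length(filter_paths(paths, g_loose, 0.10))
  expect_lte(n_strict, n_loose)
})

test_that("hub threshold is the nearest-rank percentile with ties included", {
  deg <- c(5, 5, 4, 3, 2, 1, 1, 1, 1, 1)
  net <- structure(list(
    graph = igraph::make_empty_graph(directed = FALSE),
    nodes = tibble::tibble(node = sprintf("n%02d", 1:10),
                           degree = as.integer(deg)),
    n_paths = 0L), class = "sp_network")
  hubs <- call_hubs(net, 90)
  expect_equal(attr(hubs, "degree_threshold"), 5L)
  expect_equal(sum(hubs$is_hub), 2)

  net$nodes$degree <- rep(3L, 10)
  expect_true(all(call_hubs(net, 90)$is_hub))   # all-tied: everyone is a hub

  net$nodes <- net$nodes[1, ]
  expect_true(call_hubs(net, 90)$is_hub)        # single node is the hub
})

test_that("hub class composition reports counts and RBP percentages", {
  hubs <- tibble::tibble(node = paste0("P", 1:4),
                         gene = paste0("G", 1:4),
                         degree = c(9L, 8L, 7L, 1L),
                         is_hub = c(TRUE, TRUE, TRUE, FALSE))
  anno <- tibble::tibble(gene = paste0("G", 1:4),
                         is_rbp = c(TRUE, TRUE, TRUE, FALSE),
                         rbp_class = c("rRBP", "rRBP", "mRBP", "none"))
  comp <- hub_composition(hubs, anno)
  expect_equal(comp$n[comp$rbp_class == "rRBP"], 2L)
  expect_equal(comp$pct_of_rbp_hubs[comp$rbp_class == "rRBP"], 200 / 3,
               tolerance = 1e-9)
  expect_equal(sum(comp$n), 3L)

  expect_warning(hub_composition(
    dplyr::mutate(hubs, is_hub = c(FALSE, FALSE, FALSE, TRUE)), anno),
    "No RBP")
})

test_that("IQR split assigns low/high by interpolated quartiles", {
  hubs <- tibble::tibble(node = paste0("P", 1:8), gene = paste0("G", 1:8),
                         degree = 8:1, is_hub = TRUE)
  expr <- matrix(rep(1:8, each = 6), nrow = 8, byrow = FALSE,
                 dimnames = list(paste0("G", 1:8), paste0("s", 1:6)))
  expr <- expr + matrix(rnorm(48, sd = 1e-3), 8)
  smp <- tibble::tibble(sample = paste0("s", 1:6),
                        group = rep(c("HSC", "LSC"), each = 3))
  out <- split_hubs_by_expression(hubs, expr, smp, c("HSC", "LSC"))
  expect_setequal(out$gene[out$expression_group == "low"], c("G1", "G2"))
  expect_setequal(out$gene[out$expression_group == "high"], c("G7", "G8"))
  expect_true(all(is.na(out$wilcox_p[out$expression_group == "none"])))
  expect_true(all(out$wilcox_p[out$significant] < 0.05))

  flat <- matrix(5, nrow = 8, ncol = 6,
                 dimnames = dimnames(expr))
  expect_warning(split_hubs_by_expression(hubs, flat, smp, c("HSC", "LSC")),
                 "All hub means equal")
})
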