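# End-to-end orchestration: simulate -> dge -> coexpress -> network ->
# report, with one master seed feeding named per-stage substreams and every
# artifact persisted as deterministic TSV.

#' Build a pipeline configuration
#'
#' Parameters for a full synthetic-data run of the pipeline. The simulation
#' block describes the planted truth (four myeloid cell states, a planted
#' DE contrast, three planted co-expression modules among the RBP genes, a
#' PPI with planted hubs); the analysis block holds the thresholds of every
#' stage.
#'
#' @param outdir Output directory for stage artifacts and the report.
#' @param seed Master integer seed; per-stage seeds are derived from it.
#' @param n_genes,n_rbp Simulation size (default 600 genes, 200 RBPs).
#' @param groups Named replicate counts per cell state.
#' @param contrast `c(reference, test)` for the DE and network stages.
#' @param n_de_rbp,n_de_other Planted DE genes (RBP / non-RBP) at
#'   `|log2fc| = de_lfc`.
#' @param de_lfc Planted absolute log2 fold change.
#' @param module_sizes,module_rho Sizes and target within-module Spearman
#'   correlations of the planted RBP modules.
#' @param min_count,lfc_min,alpha Low-count filter, DE fold-change and FDR
#'   thresholds.
#' @param k_modules,k_clusters Module count for co-expression detection and
#'   cluster count for DE-pattern clustering.
#' @param min_score,percentile,max_paths_per_pair Network-stage parameters.
#' @param n_hubs,d_min,frac_below_500 Planted-hub parameters of the PPI
#'   simulation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("rbphub_run_"),
                            seed = 1,
                            n_genes = 600, n_rbp = 200,
                            groups = c(HSC = 4, CMP = 4, GMP = 4, Mono = 4),
                            contrast = c("HSC", "Mono"),
                            n_de_rbp = 60, n_de_other = 40, de_lfc = 2,
                            module_sizes = c(40, 40, 40),
                            module_rho = c(0.8, 0.7, 0.6),
                            min_count = 10, lfc_min = 1.5, alpha = 0.05,
                            k_modules = 3, k_clusters = 4,
                            min_score = 500, percentile = 90,
                            max_paths_per_pair = 100,
                            n_hubs = 2, d_min = 10, frac_below_500 = 0.1) {
  cfg <- list(outdir = outdir, seed = as.integer(seed),
              n_genes = n_genes, n_rbp = n_rbp,
              groups = as.list(groups), contrast = contrast,
              n_de_rbp = n_de_rbp, n_de_other = n_de_other, de_lfc = de_lfc,
              module_sizes = module_sizes, module_rho = module_rho,
              min_count = min_count, lfc_min = lfc_min, alpha = alpha,
              k_modules = k_modules, k_clusters = k_clusters,
              min_score = min_score, percentile = percentile,
              max_paths_per_pair = max_paths_per_pair,
              n_hubs = n_hubs, d_min = d_min,
              frac_below_500 = frac_below_500)
  stopifnot(cfg$lfc_min >= 0, cfg$alpha > 0, cfg$alpha <= 1,
            cfg$k_modules >= 1, cfg$k_clusters >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration
#'
#' Configurations round-trip through a YAML key-value file.
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `read_config` returns a `pipeline_config`; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$groups <- unlist(raw$groups)
  do.call(pipeline_config, raw[setdiff(names(raw), "outdir")] |>
            c(list(outdir = raw$outdir)))
}

# Build the sim_config for the pipeline's synthetic scenario: planted DE
# genes are the first RBP genes (plus some non-RBPs), planted modules are
# the following RBP genes. Disjoint by construction so module correlation
# does not confound planted fold changes.
pipeline_sim_config <- function(cfg) {
  genes <- sim_gene_ids(cfg$n_genes)
  rbp <- genes[seq_len(cfg$n_rbp)]
  other <- setdiff(genes, rbp)
  n_up <- ceiling(cfg$n_de_rbp / 2)
  de_rbp <- rbp[seq_len(cfg$n_de_rbp)]
  de_other <- other[seq_len(cfg$n_de_other)]
  planted <- list(
    list(genes = de_rbp[seq_len(n_up)], contrast = cfg$contrast,
         log2fc = cfg$de_lfc),
    list(genes = de_rbp[(n_up + 1):cfg$n_de_rbp], contrast = cfg$contrast,
         log2fc = -cfg$de_lfc),
    list(genes = de_other, contrast = cfg$contrast, log2fc = cfg$de_lfc))
  pool <- setdiff(rbp, de_rbp)
  if (sum(cfg$module_sizes) > length(pool))
    abort("Planted modules exceed the available non-DE RBP genes.")
  offs <- cumsum(c(0, cfg$module_sizes))
  modules <- lapply(seq_along(cfg$module_sizes), function(i) {
    list(genes = pool[(offs[i] + 1):offs[i + 1]], rho = cfg$module_rho[i])
  })
  sim_config(n_genes = cfg$n_genes, n_rbp = cfg$n_rbp,
             groups = unlist(cfg$groups), planted_de = planted,
             modules = modules, seed = cfg$seed)
}

#' Run the full pipeline on synthetic data
#'
#' Stages in order: simulate counts and PPI, low-count filter,
#' normalisation and shifted-log transform, NB Wald differential
#' expression, DE selection and expression-pattern clustering, RBP
#' co-expression modules with cell-state contrasts and class composition,
#' sample structure, module/DE set intersections, and the
#' DE-constrained shortest-path network with hub calling, hub class
#' composition and the IQR expression split. All artifacts are written to
#' `config$outdir` as deterministic TSVs plus a plain-text `report.txt` of
#' stage counts; identical config and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate object and the report
#'   lines.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  rpt <- character()
  note <- function(...) rpt <<- c(rpt, sprintf(...))

  # --- simulate -------------------------------------------------------
  scfg <- pipeline_sim_config(config)
  sim <- simulate_counts(scfg)
  truth_de <- unique(sim$truth$de$gene)
  note("simulated genes: %d (%d RBP), samples: %d", nrow(sim$counts),
       sum(sim$annotation$is_rbp), ncol(sim$counts))
  write_counts(sim$counts, out("counts.tsv"))
  write_table(sim$samples, out("samples.tsv"))
  write_table(sim$annotation, out("annotation.tsv"))

  attach_to <- intersect(truth_de,
                         sim$annotation$gene[sim$annotation$is_rbp])
  ppi <- simulate_ppi(rownames(sim$counts), attach_to,
                      n_hubs = config$n_hubs, d_min = config$d_min,
                      frac_below_500 = config$frac_below_500,
                      seed = config$seed + 1L)
  note("simulated PPI edges: %d (planted hubs: %d)", nrow(ppi$edges),
       length(ppi$truth$hub_genes))
  write_edge_list(ppi$edges, out("edges.tsv"))
  write_table(ppi$idmap, out("idmap.tsv"))

  # --- dge ------------------------------------------------------------
  filtered <- filter_low_counts(sim$counts, config$min_count)
  note("genes after low-count filter (min_count = %d): %d",
       config$min_count, nrow(filtered))
  sf <- size_factors(filtered)
  expr <- transform_log(filtered, sf)
  fit <- wald_test(filtered, sim$samples, config$contrast)
  write_table(fit$table, out("de_table.tsv"))
  de_genes <- select_de(fit, config$lfc_min, config$alpha)
  note("DE genes (|log2fc| >= %.2f, padj <= %.2f): %d",
       config$lfc_min, config$alpha, length(de_genes))
  readr::write_lines(sort(de_genes), out("de_genes.txt"))

  clusters <- NULL
  if (length(de_genes) >= config$k_clusters) {
    clusters <- cluster_rows(expr[de_genes, , drop = FALSE],
                             config$k_clusters)
    write_table(clusters, out("de_clusters.tsv"))
    note("DE expression-pattern clusters: %s",
         paste(sprintf("C%d=%d", seq_len(config$k_clusters),
                       tabulate(clusters$cluster, config$k_clusters)),
               collapse = " "))
  } else note("DE expression-pattern clusters: skipped (too few DE genes)")

  # --- coexpression ---------------------------------------------------
  rbp_expr <- expr[rownames(expr) %in%
                     sim$annotation$gene[sim$annotation$is_rbp], ,
                   drop = FALSE]
  corr <- suppressWarnings(gene_spearman(rbp_expr))
  modules <- detect_modules(corr, config$k_modules)
  write_table(modules, out("modules.tsv"))
  note("co-expression modules (k = %d): %s", config$k_modules,
       paste(sprintf("%d=%d", seq_len(config$k_modules),
                     tabulate(modules$module, config$k_modules)),
             collapse = " "))
  msum <- summarize_module(modules, rbp_expr, sim$samples)
  write_table(msum$medians, out("module_medians.tsv"))
  write_table(msum$tests, out("module_tests.tsv"))
  comp <- class_composition(modules, sim$annotation)
  write_table(comp, out("module_classes.tsv"))

  struct <- sample_structure(expr)
  write_table(struct$pca$scores, out("pca_scores.tsv"))
  write_table(tibble(component = seq_along(struct$pca$variance_ratio),
                     variance_ratio = struct$pca$variance_ratio),
              out("pca_variance.tsv"), sort = FALSE)
  note("PCA variance explained by 3 components: %.1f%%",
       100 * sum(struct$pca$variance_ratio[1:3]))

  mod_sets <- split(modules$gene, paste0("module_", modules$module))
  isect <- set_intersections(c(list(DE = de_genes), mod_sets))
  write_table(isect, out("set_intersections.tsv"), sort = FALSE)

  # --- network --------------------------------------------------------
  graph <- build_graph(ppi$edges, config$min_score)
  note("PPI after score filter (>= %d): %d nodes, %d edges",
       config$min_score, igraph::vcount(graph), igraph::ecount(graph))
  graph <- suppressMessages(
    annotate_graph(graph, ppi$idmap, fit, sim$annotation))
  eps <- rbp_nodes(graph)
  paths <- suppressMessages(
    shortest_path_set(graph, eps, config$max_paths_per_pair))
  note("shortest paths computed: %d (truncated pairs: %d)",
       length(paths), attr(paths, "truncated_pairs"))
  kept <- filter_paths(paths, graph, config$alpha)
  note("paths retained after DE filter (padj <= %.2f): %d",
       config$alpha, length(kept))
  net <- suppressWarnings(union_network(kept, graph))
  note("union network: %d nodes, %d edges", nrow(net$nodes),
       igraph::ecount(net$graph))
  if (nrow(net$nodes) > 0) {
    write_table(tibble(node_a = igraph::as_edgelist(net$graph)[, 1],
                       node_b = igraph::as_edgelist(net$graph)[, 2]),
                out("sp_network_edges.tsv"))
    hubs <- call_hubs(net, config$percentile)
    write_table(hubs, out("hubs.tsv"))
    note("hub nodes (top %g percentile, degree >= %d): %d",
         100 - config$percentile, attr(hubs, "degree_threshold"),
         sum(hubs$is_hub))
    hcomp <- hub_composition(hubs, sim$annotation)
    write_table(hcomp, out("hub_classes.tsv"))
    split_tbl <- split_hubs_by_expression(
      hubs[hubs$is_hub, , drop = FALSE], expr, sim$samples, config$contrast)
    write_table(split_tbl, out("hub_expression_split.tsv"))
    note("hub expression split: low = %d, high = %d, significant = %d",
         sum(split_tbl$expression_group == "low"),
         sum(split_tbl$expression_group == "high"),
         sum(split_tbl$significant))
    recovered <- ppi$truth$hub_proteins %in% hubs$node[hubs$is_hub]
    note("planted hubs recovered: %d / %d", sum(recovered), length(recovered))
  } else {
    hubs <- NULL; hcomp <- NULL; split_tbl <- NULL
    note("hub calling skipped: empty union network")
  }

  readr::write_lines(rpt, out("report.txt"))
  invisible(list(config = config, sim = sim, ppi = ppi,
                 filtered = filtered, expr = expr, fit = fit,
                 de_genes = de_genes, clusters = clusters,
                 modules = modules, module_summary = msum,
                 class_composition = comp, structure = struct,
                 intersections = isect, graph = graph, paths = paths,
                 kept_paths = kept, network = net, hubs = hubs,
                 hub_composition = hcomp, hub_split = split_tbl,
                 report = rpt))
}
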