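# Synthetic-data generator: negative-binomial count matrices with planted
# fold changes, correlated gene blocks (modules) and library-size variation,
# plus preferential-attachment PPI graphs with planted hubs. The planted
# ground truth makes every downstream stage testable at desk scale.

# Log-sd of the shared per-module latent factor. Fixed; the factor weight w
# below is what is calibrated against the target Spearman correlation.
MODULE_SIGMA <- 1

# Empirical calibration of latent-factor weight w against the attained
# within-module Spearman correlation, at the generator defaults
# (sigma = 1, dispersion 0.1, lognormal baseline meanlog 5 / sdlog 1,
# 24 samples). Computed once by scripts in the package sources; linearly
# interpolated at run time.
MODULE_RHO_TABLE <- data.frame(
  rho = c(0.000, 0.005, 0.025, 0.058, 0.109, 0.169, 0.250, 0.346, 0.465,
          0.618, 0.705, 0.810),
  w   = c(0.00, 0.10, 0.20, 0.30, 0.40, 0.50, 0.60, 0.70, 0.80,
          0.90, 0.95, 1.00)
)

module_factor_weight <- function(rho) {
  stats::approx(MODULE_RHO_TABLE$rho, MODULE_RHO_TABLE$w, xout = rho,
                rule = 2)$y
}

#' Build a simulation configuration
#'
#' Describes the generative model for a synthetic count matrix: per-gene
#' lognormal baseline expression, negative-binomial sampling with gene-level
#' dispersion, per-sample multiplicative size factors, group-specific
#' planted log2 fold changes, and co-expression modules induced by a shared
#' per-module, per-sample lognormal latent factor whose weight is calibrated
#' to a target within-module Spearman correlation.
#'
#' @param n_genes Total number of genes.
#' @param n_rbp Number of genes flagged as RBPs (the first `n_rbp` genes);
#'   RBP class labels are assigned round-robin over the nine-class
#'   vocabulary.
#' @param groups Named integer vector of replicates per cell-state label,
#'   e.g. `c(HSC = 4, CMP = 4)`. Every group needs >= 2 replicates.
#' @param planted_de List of effects, each a list with elements `genes`
#'   (character), `contrast` (character length 2: reference, test) and
#'   `log2fc` (scalar): the test group's mean is shifted by `2^log2fc` for
#'   those genes. Gene sets must be disjoint within a contrast.
#' @param modules List of planted co-expression blocks, each a list with
#'   elements `genes` (character) and `rho` (target within-module Spearman
#'   correlation in `[0, 1)`). Module gene sets must be disjoint.
#' @param baseline_meanlog,baseline_sdlog Parameters of the lognormal draw
#'   of per-gene expected normalized counts (defaults 5 and 1, i.e. a
#'   median of ~148 counts).
#' @param dispersion Negative-binomial dispersion alpha (variance
#'   `mu + alpha * mu^2`); 0 gives Poisson sampling. Default 0.1, a typical
#'   bulk RNA-seq value.
#' @param libsize_range Range of the uniform draw of per-sample
#'   multiplicative size factors. Default `c(0.5, 2)`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       n_rbp = 300,
                       groups = c(HSC = 4, CMP = 4, GMP = 4, Mono = 4),
                       planted_de = list(),
                       modules = list(),
                       baseline_meanlog = 5,
                       baseline_sdlog = 1,
                       dispersion = 0.1,
                       libsize_range = c(0.5, 2),
                       seed = 1) {
  if (n_rbp > n_genes) abort("`n_rbp` cannot exceed `n_genes`.")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    abort("`groups` must be a named vector of replicate counts.")
  if (any(groups < 2)) abort("Every group needs at least 2 replicates.")
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  if (libsize_range[1] <= 0 || libsize_range[2] < libsize_range[1])
    abort("`libsize_range` must be positive and increasing.")
  for (m in modules) {
    if (m$rho < 0 || m$rho >= 1)
      abort("Module target correlation must lie in [0, 1).")
  }
  mod_genes <- unlist(lapply(modules, `[[`, "genes"))
  if (anyDuplicated(mod_genes)) abort("Module gene sets must be disjoint.")
  for (ct in split(planted_de, vapply(planted_de, function(e)
    paste(e$contrast, collapse = "|"), character(1)))) {
    g <- unlist(lapply(ct, `[[`, "genes"))
    if (anyDuplicated(g))
      abort("Planted DE gene sets must be disjoint within a contrast.")
  }
  structure(list(
    n_genes = n_genes, n_rbp = n_rbp, groups = groups,
    planted_de = planted_de, modules = modules,
    baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
    dispersion = dispersion, libsize_range = libsize_range,
    seed = as.integer(seed)), class = "sim_config")
}

#' Default gene identifiers for a simulation
#'
#' @param n Number of genes.
#' @return Character vector `g0001 ...` (zero-padded).
#' @export
sim_gene_ids <- function(n) sprintf("g%0*d", max(4, nchar(n)), seq_len(n))

#' Simulate a count matrix with planted ground truth
#'
#' Counts are drawn as negative binomial with mean
#' `mu_gs = s_s * q_g * 2^beta_(g, group(s)) * f_(m(g), s)` and variance
#' `mu + alpha * mu^2`, where `s_s` is the sample size factor, `q_g` the
#' lognormal baseline, `beta` the planted group effect and `f` a shared
#' per-module lognormal latent factor (mean 1) that induces the target
#' within-module Spearman correlation.
#'
#' @param config A [sim_config()].
#' @return List with elements `counts` (integer matrix), `samples`
#'   (tibble: sample, group, replicate), `annotation` (tibble: gene,
#'   is_rbp, rbp_class) and `truth` (list: `de` tibble of planted effects,
#'   `modules` tibble of planted module labels, `size_factors` tibble).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sim_gene_ids(config$n_genes)
  grp <- rep(names(config$groups), times = config$groups)
  repl <- unlist(lapply(config$groups, seq_len), use.names = FALSE)
  samples <- tibble(sample = paste0(grp, "_", repl), group = grp,
                    replicate = repl)
  n_s <- nrow(samples)

  q <- rlnorm(config$n_genes, config$baseline_meanlog, config$baseline_sdlog)
  s <- runif(n_s, config$libsize_range[1], config$libsize_range[2])

  beta <- matrix(0, config$n_genes, length(config$groups),
                 dimnames = list(genes, names(config$groups)))
  de_truth <- list()
  for (eff in config$planted_de) {
    missing_grp <- setdiff(eff$contrast, names(config$groups))
    if (length(missing_grp) > 0)
      abort(paste0("Unknown group in planted_de contrast: ", missing_grp[1]))
    idx <- match(eff$genes, genes)
    if (anyNA(idx)) abort("planted_de names a gene outside the simulation.")
    beta[idx, eff$contrast[2]] <- beta[idx, eff$contrast[2]] + eff$log2fc
    de_truth[[length(de_truth) + 1]] <- tibble(
      gene = eff$genes, reference = eff$contrast[1], test = eff$contrast[2],
      log2fc = eff$log2fc)
  }

  # Shared latent factor per module: u = w z_module + sqrt(1-w^2) e_gene,
  # exponentiated with mean correction so planted fold changes are preserved.
  log_mult <- matrix(0, config$n_genes, n_s)
  mod_truth <- tibble(gene = character(), module = integer())
  for (i in seq_along(config$modules)) {
    mod <- config$modules[[i]]
    idx <- match(mod$genes, genes)
    if (anyNA(idx)) abort("modules name a gene outside the simulation.")
    w <- module_factor_weight(mod$rho)
    z <- rnorm(n_s)
    e <- matrix(rnorm(length(idx) * n_s), length(idx), n_s)
    u <- w * matrix(z, length(idx), n_s, byrow = TRUE) + sqrt(1 - w^2) * e
    log_mult[idx, ] <- MODULE_SIGMA * u - MODULE_SIGMA^2 / 2
    mod_truth <- dplyr::bind_rows(mod_truth,
                                  tibble(gene = mod$genes, module = i))
  }

  mu <- (q * 2^beta[, samples$group, drop = FALSE]) * exp(log_mult)
  mu <- sweep(mu, 2, s, `*`)
  counts <- matrix(
    if (config$dispersion == 0) stats::rpois(length(mu), lambda = mu)
    else rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
    nrow = config$n_genes, dimnames = list(genes, samples$sample))
  storage.mode(counts) <- "integer"

  classes <- rep("none", config$n_genes)
  if (config$n_rbp > 0)
    classes[seq_len(config$n_rbp)] <-
      rep_len(RBP_CLASSES, config$n_rbp)
  annotation <- tibble(gene = genes,
                       is_rbp = seq_len(config$n_genes) <= config$n_rbp,
                       rbp_class = classes)

  list(counts = counts, samples = samples, annotation = annotation,
       truth = list(
         de = if (length(de_truth)) dplyr::bind_rows(de_truth)
              else tibble(gene = character(), reference = character(),
                          test = character(), log2fc = double()),
         modules = mod_truth,
         size_factors = tibble(sample = samples$sample, size_factor = s)))
}

#' Simulate a PPI graph with planted hubs
#'
#' A scale-free background graph is drawn by preferential attachment over
#' one protein per gene (identity-suffixed identifiers). A planted hub set
#' of `n_hubs` nodes, drawn from `attach_to`, is each wired to `d_min`
#' further nodes of `attach_to`. Background edge confidence scores are
#' uniform on 500-1000 with a configurable fraction pushed below 500 to
#' exercise the downstream confidence filter; planted hub edges always
#' score >= 500 so the planted ground truth survives that filter (unless
#' `frac_below_500 = 1`, which forces every edge below the threshold).
#'
#' @param genes Character vector of gene identifiers (typically the genes
#'   of a companion simulated count matrix).
#' @param attach_to Character vector of genes (e.g. planted DE RBP genes)
#'   from which hubs and their neighbours are drawn.
#' @param n_hubs Number of planted hub nodes.
#' @param d_min Planted edges per hub into `attach_to`.
#' @param frac_below_500 Fraction of background edges forced to a score in
#'   400-499.
#' @param pa_m Edges added per step of the preferential-attachment process.
#' @param seed Integer seed.
#' @return List with `edges` (canonical tibble), `idmap` (tibble gene,
#'   protein) and `truth` (list: `hub_genes`, `hub_proteins`).
#' @export
simulate_ppi <- function(genes, attach_to, n_hubs = 2, d_min = 10,
                         frac_below_500 = 0.1, pa_m = 2, seed = 1) {
  if (!all(attach_to %in% genes)) abort("`attach_to` must be a subset of `genes`.")
  if (d_min > length(attach_to) - 1)
    abort("`d_min` exceeds the number of available attachment nodes.")
  set.seed(seed)
  n <- length(genes)
  prot <- setNames(paste0(genes, "_p"), genes)
  idmap <- tibble(gene = genes, protein = unname(prot))

  g_bg <- igraph::sample_pa(n, power = 1, m = pa_m, directed = FALSE)
  # decouple preferential-attachment age from gene identity
  perm <- sample(genes)
  el <- igraph::as_edgelist(g_bg, names = FALSE)
  bg <- tibble(node_a = prot[perm[el[, 1]]], node_b = prot[perm[el[, 2]]])
  n_bg <- nrow(bg)
  bg$combined_score <- round(runif(n_bg, 500, 1000))
  n_low <- round(frac_below_500 * n_bg)
  if (n_low > 0) {
    low_idx <- sample.int(n_bg, n_low)
    bg$combined_score[low_idx] <- round(runif(n_low, 400, 499))
  }

  hub_genes <- sample(attach_to, n_hubs)
  planted <- purrr::map_dfr(hub_genes, function(h) {
    nb <- sample(setdiff(attach_to, h), d_min)
    tibble(node_a = prot[[h]], node_b = unname(prot[nb]),
           combined_score = round(runif(d_min, 500, 1000)))
  })
  if (frac_below_500 >= 1)
    planted$combined_score <- round(runif(nrow(planted), 400, 499))

  edges <- suppressMessages(canonicalize_edges(dplyr::bind_rows(bg, planted)))
  list(edges = edges, idmap = idmap,
       truth = list(hub_genes = hub_genes,
                    hub_proteins = unname(prot[hub_genes])))
}
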