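# rbphub

Analysis of RNA-binding-protein (RBP) gene expression across normal
myeloid and leukemic cell states, from a gene × sample read-count matrix
to co-expression modules, differential expression, and
differential-expression-constrained shortest-path hub calling on a
protein–protein interaction (PPI) network.

RBPs are increasingly recognised as regulators of hematopoietic
differentiation and of leukemic transformation, but single-gene
differential expression misses how they act in concert. `rbphub` is for
computational biologists who have bulk RNA-seq counts over cell states
(e.g. HSC → CMP → GMP → monocyte, or HSC vs LSC/blast in AML), an RBP
annotation, and a STRING-style interactome, and who want a reproducible,
tested version of the combined module/DE/network-hub workflow — plus a
synthetic-data generator with planted ground truth to validate every
stage.

## What it computes

**Differential expression.** Counts are modelled as negative binomial,
NB(μ, α) with Var = μ + αμ², normalized by median-of-ratios size
factors. For a two-group contrast the Wald statistic is

    lfĉ = log2((m̄_test + c) / (m̄_ref + c)),   z = lfĉ / SE(lfĉ)

with pseudocount c = 0.5 on normalized group means, a delta-method
standard error from the NB variance, method-of-moments dispersion with
conservative moderation, and Benjamini–Hochberg FDR control. Genes pass
with |lfĉ| ≥ 1.5 and padj ≤ 0.05 (both inclusive), then cluster into
expression-pattern clusters (C1–C4 style) by average-linkage clustering
of z-scored profiles.

**Co-expression modules.** Gene–gene Spearman correlation over all
samples, average-linkage clustering under distance 1 − ρ cut to k
modules (numbered by decreasing size), per-module cell-state contrasts
by Wilcoxon rank-sum (exact for small untied samples), RBP-class
composition, PCA / sample-correlation structure, and UpSet-style
exclusive set intersections.

**Shortest-path hub analysis.** The PPI keeps edges with STRING combined
score ≥ 500. All unweighted shortest paths between every pair of RBP
nodes are enumerated on the full filtered graph, then only paths whose
*every* node is differentially expressed (padj ≤ 0.05) are retained.
Their union forms the shortest-path network; nodes whose degree reaches
the nearest-rank 90th percentile (ties included) are hubs, reported with
RBP class composition and an IQR-based low/high expression split with
per-gene Wilcoxon tests.

**Synthetic data.** `simulate_counts()` plants fold changes and
correlated gene blocks (shared log-normal latent factors calibrated to a
target Spearman ρ) in NB counts with library-size variation;
`simulate_ppi()` plants high-degree hubs in a preferential-attachment
graph. Identical seeds give byte-identical data.

## Worked example

```r
library(rbphub)

cfg <- pipeline_config(outdir = "rbphub_demo", seed = 1)
res <- run_pipeline(cfg)
writeLines(res$report)
```

```
simulated genes: 600 (200 RBP), samples: 16
simulated PPI edges: 1217 (planted hubs: 2)
genes after low-count filter (min_count = 10): 600
DE genes (|log2fc| >= 1.50, padj <= 0.05): 87
DE expression-pattern clusters: C1=56 C2=28 C3=2 C4=1
co-expression modules (k = 3): 1=117 2=77 3=6
PCA variance explained by 3 components: 65.7%
PPI after score filter (>= 500): 598 nodes, 1097 edges
shortest paths computed: 49758 (truncated pairs: 0)
paths retained after DE filter (padj <= 0.05): 413
union network: 41 nodes, 43 edges
hub nodes (top 10 percentile, degree >= 3): 8
hub expression split: low = 2, high = 2, significant = 3
planted hubs recovered: 2 / 2
```

The run plants 100 DE genes at |log2FC| = 2 between HSC and monocyte
samples (87 recovered at the 1.5/0.05 thresholds), three correlated RBP
modules, and two PPI hubs wired into the significant genes — both of
which come back as called hubs. Each fitted object is a tibble or has
broom-style accessors:

```r
glance(res$fit)
#> # A tibble: 1 × 7
#>   reference test  n_genes n_samples  n_de lfc_min alpha
#> 1 HSC       Mono      600         8    87     1.5  0.05

head(res$hubs, 3)
#> # A tibble: 3 × 8
#>   node    degree gene  is_rbp rbp_class log2fc    padj is_hub
#> 1 g0006_p     11 g0006 TRUE   snoRBP     1.31  8.47e-4 TRUE
#> 2 g0039_p     10 g0039 TRUE   rrRBP     -1.73  1.88e-2 TRUE
#> 3 g0132_p      6 g0132 TRUE   snoRBP    -0.990 3.35e-2 TRUE
```

`autoplot(res$fit)` draws the volcano plot; `plot_module_expression()`,
`plot_pca()` and `plot_degree_distribution()` cover the other result
types. A thin command-line wrapper with `simulate` / `dge` / `coexpress`
/ `structure` / `network` / `all` subcommands lives at
`inst/cli/rbphub.R`. The methods vignette
(`vignettes/rbphub-methods.Rmd`) documents the model, every tunable
parameter and the design decisions.

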