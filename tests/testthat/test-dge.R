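# Filtering, normalization, dispersion, the Wald test and DE-pattern
# clustering.

mk_counts <- function(x, genes = NULL, samples = NULL) {
  m <- if (is.matrix(x)) x else matrix(x, nrow = length(x) / 2)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  storage.mode(m) <- "integer"
  m
}

test_that("low-count filter removes a gene only when every sample is low", {
  m <- mk_counts(matrix(c(9, 9, 9, 9,
                          9, 10, 0, 0,
                          0, 0, 0, 0), nrow = 3, byrow = TRUE),
                 genes = c("alllow", "onehigh", "zero"))
  out <- filter_low_counts(m, 10)
  expect_identical(rownames(out), "onehigh")
  expect_identical(colnames(out), colnames(m))
  expect_warning(filter_low_counts(mk_counts(matrix(0L, 2, 2)), 10),
                 "All genes removed")
})

test_that("median-of-ratios size factors match the hand computation", {
  m <- mk_counts(matrix(c(10, 20, 30, 60, 50, 100), nrow = 3, byrow = TRUE))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)

  same <- mk_counts(matrix(rep(c(5, 9, 14), 3), nrow = 3))
  expect_true(all(abs(size_factors(same) - 1) < 1e-12))

  nopos <- mk_counts(matrix(c(0, 3, 5, 0), 2, byrow = TRUE))
  expect_error(size_factors(nopos), "pseudocount")
  expect_silent(size_factors(nopos, pseudocount = 1))
})

test_that("shifted-log transform has the stated fixed points and invariance", {
  m <- mk_counts(matrix(c(0, 7, 3, 1), 2, byrow = TRUE))
  tr <- transform_log(m, factors = c(1, 1))
  expect_equal(tr["g1", "s1"], 0)          # log2(0/1 + 1)
  expect_equal(tr["g1", "s2"], 3)          # log2(7/1 + 1)
  tr2 <- transform_log(mk_counts(matrix(c(0, 14, 6, 2), 2, byrow = TRUE)),
                       factors = c(2, 2))
  expect_equal(tr2, tr, ignore_attr = TRUE)
})

test_that("method-of-moments dispersion floors at zero variance and is consistent", {
  smp <- tibble::tibble(sample = paste0("s", 1:4), group = rep("A", 4))
  const <- mk_counts(matrix(10L, 1, 4))
  expect_equal(unname(estimate_dispersion(const, smp, factors = rep(1, 4))),
               1e-8)

  set.seed(42)
  n <- 200
  smp2 <- tibble::tibble(sample = paste0("s", 1:n), group = rep("A", n))
  pois <- mk_counts(matrix(rpois(2 * n, 150), 2, n))
  a_pois <- estimate_dispersion(pois, smp2, factors = rep(1, n))
  expect_lt(max(a_pois), 0.02)
  nb <- mk_counts(matrix(rnbinom(2 * n, mu = 150, size = 5), 2, n))
  a_nb <- estimate_dispersion(nb, smp2, factors = rep(1, n))
  expect_lt(max(abs(a_nb - 0.2)), 0.05)
})

test_that("Wald fold change follows the pseudocounted group-mean formula", {
  set.seed(1)
  n <- 4
  m <- mk_counts(rbind(c(rpois(n, 400), rpois(n, 100)),
                       c(rpois(n, 200), rpois(n, 200))),
                 samples = paste0("s", 1:(2 * n)))
  smp <- tibble::tibble(sample = colnames(m),
                        group = rep(c("ref", "tst"), each = n))
  fit <- wald_test(m, smp, c("ref", "tst"))
  tb <- tidy(fit)
  norm <- sweep(m, 2, fit$size_factors, `/`)
  m_ref <- rowMeans(norm[, 1:n]); m_tst <- rowMeans(norm[, n + 1:n])
  expect_equal(tb$log2fc, unname(log2((m_tst + 0.5) / (m_ref + 0.5))))
  expect_true(all(tb$pvalue >= 0 & tb$pvalue <= 1))
  expect_true(all(tb$padj >= tb$pvalue))   # BH can only raise p

  # the worked numeric case: normalized group means 100 vs 25
  expect_equal(log2((25 + 0.5) / (100 + 0.5)), -1.978, tolerance = 1e-3)
})

test_that("swapping the contrast negates log2fc and preserves p-values", {
  set.seed(2)
  m <- mk_counts(matrix(rnbinom(50 * 8, mu = 200, size = 10), 50, 8))
  smp <- tibble::tibble(sample = colnames(m),
                        group = rep(c("A", "B"), each = 4))
  ab <- tidy(wald_test(m, smp, c("A", "B")))
  ba <- tidy(wald_test(m, smp, c("B", "A")))
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$pvalue, ba$pvalue)
})

test_that("identical groups give exactly zero fold change", {
  m <- mk_counts(matrix(rep(c(30L, 80L, 120L), 4), nrow = 3))
  smp <- tibble::tibble(sample = colnames(m),
                        group = rep(c("A", "B"), each = 2))
  tb <- tidy(wald_test(m, smp, c("A", "B")))
  expect_equal(tb$log2fc, rep(0, 3))
  expect_error(wald_test(m, smp, c("A", "C")), "absent")
})

test_that("BH adjustment reproduces the enumerated step-up case", {
  p <- c(0.005, 0.01, 0.03, 0.04)
  expect_equal(p.adjust(p, "BH"), c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_oracle(p), c(0.02, 0.02, 0.04, 0.04))
})

test_that("DE selection thresholds are inclusive on both boundaries", {
  tb <- tibble::tibble(
    gene = c("sel", "padj_fail", "boundary", "lfc_fail"),
    log2fc = c(1.6, 1.6, -1.5, 1.4),
    padj = c(0.01, 0.06, 0.05, 0.01))
  expect_setequal(select_de(tb), c("sel", "boundary"))
})

test_that("row z-scoring centres, scales and zeroes constant rows", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  expect_warning(z <- zscore_rows(m), "constant")
  expect_equal(z["a", ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(z["b", ], c(0, 0, 0), ignore_attr = TRUE)
  expect_true(all(abs(rowMeans(z)) < 1e-12))
})

test_that("pattern clustering recovers planted patterns and is order-invariant", {
  set.seed(3)
  up <- t(matrix(rep(c(0, 0, 5, 5), 10), nrow = 4)) + rnorm(40, sd = 0.1)
  dn <- t(matrix(rep(c(5, 5, 0, 0), 10), nrow = 4)) + rnorm(40, sd = 0.1)
  m <- rbind(up, dn)
  rownames(m) <- paste0("g", 1:20)
  cl <- cluster_rows(m, 2)
  expect_equal(length(unique(cl$cluster[1:10])), 1)
  expect_equal(length(unique(cl$cluster[11:20])), 1)
  expect_false(cl$cluster[1] == cl$cluster[11])

  perm <- sample(nrow(m))
  cl2 <- cluster_rows(m[perm, ], 2)
  j <- dplyr::inner_join(cl, cl2, by = "gene")
  expect_true(all((j$cluster.x == j$cluster.x[1]) ==
                    (j$cluster.y == j$cluster.y[1])))

  singles <- cluster_rows(m, nrow(m))
  expect_equal(sort(table(singles$cluster)), sort(table(seq_len(20))),
               ignore_attr = TRUE)
  expect_error(cluster_rows(m, 0), ">= 1")
})
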