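# One-off calibration: latent factor weight w -> attained within-module
# Spearman rho, at generator defaults (sigma=1, alpha=0.1, meanlog=5,
# sdlog=1, 24 samples). Results are frozen into MODULE_RHO_TABLE in
# R/simulate.R; rerun this script only if the generator defaults change.
suppressPackageStartupMessages(library(rbphub))

attained <- function(w, n_s = 24, n_g = 40, n_bg = 200, reps = 30) {
  out <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    q <- rlnorm(n_g + n_bg, 5, 1)
    s <- runif(n_s, 0.5, 2)
    z <- rnorm(n_s)
    e <- matrix(rnorm(n_g * n_s), n_g, n_s)
    u <- w * matrix(z, n_g, n_s, byrow = TRUE) + sqrt(1 - w^2) * e
    logm <- rbind(u - 0.5, matrix(0, n_bg, n_s))
    mu <- sweep(q * exp(logm), 2, s, `*`)
    cts <- matrix(rnbinom(length(mu), mu = mu, size = 10), n_g + n_bg, n_s)
    rownames(cts) <- paste0("g", seq_len(n_g + n_bg))
    colnames(cts) <- paste0("s", 1:n_s)
    sf <- tryCatch(size_factors(cts), error = function(e) rep(1, n_s))
    expr <- log2(sweep(cts, 2, sf, `/`) + 1)
    rho <- cor(t(expr[1:n_g, ]), method = "spearman")
    out[r] <- mean(rho[upper.tri(rho)])
  }
  mean(out)
}

ws <- seq(0, 1, by = 0.05)
res <- sapply(ws, attained)
print(round(cbind(w = ws, rho = res), 3))
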