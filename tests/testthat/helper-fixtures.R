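# Shared fixtures and independent oracles, all generated in code.

# Random named genes-by-samples matrix.
rand_expr <- function(ng, ns, seed, sd = 1) {
  withr::with_seed(seed, {
    matrix(rnorm(ng * ns, sd = sd), ng, ns,
           dimnames = list(paste0("g", seq_len(ng)), paste0("s", seq_len(ns))))
  })
}

# Independent oracle for explained-variance fractions: dense eigendecomposition
# of the weighted covariance / second-moment matrix, bypassing the iterative
# engine entirely.
eigen_l1l2 <- function(x, w = rep(1, nrow(x)), mode = "standard", center = NULL) {
  b <- if (mode == "standard") as.vector(crossprod(x, w)) / sum(w) else center
  y <- sqrt(w) * (x - rep(b, each = nrow(x)))
  ev <- eigen(crossprod(y), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  c(L1 = ev[1] / sum(ev), L2 = ev[2] / sum(ev))
}

# Module definition built directly (not via GMT parsing).
make_module <- function(name, genes, weights = rep(1, length(genes)),
                        sign_defined = rep(FALSE, length(genes))) {
  structure(list(name = name, description = "test module",
                 genes = data.frame(gene = genes, weight = weights,
                                    sign_defined = sign_defined,
                                    stringsAsFactors = FALSE)),
            class = "roma_module")
}

# Planted single-factor matrix at a chosen per-gene signal-to-noise ratio:
# loadings +-1/sqrt(n_genes), activity sd chosen so that the per-gene signal
# standard deviation is snr * noise_sd.
planted_sim <- function(n_genes = 50, n_samples = 20, snr = 2, noise_sd = 0.5,
                        n_background = 500, seed = 1, n_factors = 1L,
                        name = "PLANT") {
  loadings <- rep(c(1, -1), length.out = n_genes)
  activity <- withr::with_seed(seed + 1000L,
    rnorm(n_samples, sd = snr * noise_sd * sqrt(n_genes)))
  spec <- planted_module_spec(name, loadings, activity,
                              noise_sd = noise_sd, n_factors = n_factors)
  simulate_expression(n_background, n_samples, specs = list(spec),
                      background_sd = 1, seed = seed)
}

# 21-gene robust-filter fixture: 20 coherent factor-driven genes plus one
# aberrant gene with 100x amplitude.
aberrant_fixture <- function(seed = 4) {
  withr::with_seed(seed, {
    act <- rnorm(12)
    load <- rnorm(20)
    load <- load / sqrt(sum(load^2))
    x <- rbind(tcrossprod(load, act) + matrix(rnorm(240, sd = 0.1), 20, 12),
               100 * rnorm(12))
    dimnames(x) <- list(c(paste0("g", 1:20), "ABERRANT"), paste0("s", 1:12))
    x - rowMeans(x)
  })
}
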