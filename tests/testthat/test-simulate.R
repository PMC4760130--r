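test_that("noiseless single-factor modules are exactly rank one", {
  spec <- planted_module_spec("PLANT", rep(c(1, -1), 6),
                              withr::with_seed(2, rnorm(8, sd = 3)),
                              noise_sd = 0)
  sim <- simulate_expression(20, 8, specs = list(spec), seed = 3)
  # planted submatrix: rank 1 after row centering
  x_mod <- sim$x[sim$modules$PLANT$genes$gene, ]
  expect_identical(qr(x_mod)$rank, 1L)
  f <- fit_pc1(x_mod, mode = "standard")
  expect_equal(f$L1, 1.0, tolerance = 1e-12)
})

test_that("generation is reproducible and validates its inputs", {
  s1 <- planted_sim(n_genes = 10, n_samples = 6, n_background = 30, seed = 7)
  s2 <- planted_sim(n_genes = 10, n_samples = 6, n_background = 30, seed = 7)
  expect_identical(s1$x, s2$x)
  expect_identical(s1$truth, s2$truth)
  s3 <- planted_sim(n_genes = 10, n_samples = 6, n_background = 30, seed = 8)
  expect_false(identical(s1$x, s3$x))

  sp <- planted_module_spec("A", c(1, -1), rnorm(5))
  expect_error(
    simulate_expression(10, 5, specs = list(sp, sp)),
    "duplicate")
  expect_error(
    simulate_expression(10, 5,
      specs = list(planted_module_spec("B", c(1, 1, 1), rnorm(4)))),
    "n_samples")
})

test_that("generated matrices are row-centered with correct labels, weights and truth records", {
  sim <- planted_sim(n_genes = 8, n_samples = 5, n_background = 12, seed = 9)
  expect_true(all(abs(rowSums(sim$x)) < 1e-9 * ncol(sim$x)))
  expect_identical(nrow(sim$x), 8L + 12L)
  g <- sim$modules$PLANT$genes
  expect_true(all(g$sign_defined))
  expect_identical(g$weight, unname(sign(sim$truth$PLANT$loadings[, 1])))
  expect_identical(rownames(sim$truth$PLANT$loadings), g$gene)
  expect_identical(dim(sim$truth$PLANT$activity), c(5L, 1L))
})

test_that("control sets come from background genes and multi-factor truth has all factors", {
  spec <- planted_module_spec("TWO", rep(c(1, -1), 10),
                              withr::with_seed(5, rnorm(12, sd = 3)),
                              noise_sd = 0.3, n_factors = 2L)
  sim <- simulate_expression(100, 12, specs = list(spec), seed = 15,
                             n_control_sets = 3, control_size = 8)
  expect_identical(dim(sim$truth$TWO$loadings), c(20L, 2L))
  expect_identical(dim(sim$truth$TWO$activity), c(12L, 2L))
  ctrl <- grep("^CONTROL", names(sim$modules), value = TRUE)
  expect_length(ctrl, 3L)
  for (nm in ctrl) {
    expect_true(all(grepl("^BG", sim$modules[[nm]]$genes$gene)))
    expect_false(any(sim$modules[[nm]]$genes$sign_defined))
  }
  expect_error(simulate_expression(5, 6, n_control_sets = 1, control_size = 9),
               "control_size")
})

test_that("PC1 recovery degrades monotonically with noise on a fixed seed", {
  n_genes <- 15
  activity <- withr::with_seed(22, rnorm(10, sd = sqrt(n_genes)))  # per-gene signal sd 1
  l1s <- vapply(c(0, 0.25, 1, 4), function(s) {
    spec <- planted_module_spec("P", rep(c(1, -1), length.out = n_genes),
                                activity, noise_sd = s)
    sim <- simulate_expression(10, 10, specs = list(spec), seed = 21)
    fit_pc1(sim$x[sim$modules$P$genes$gene, ], mode = "standard")$L1
  }, numeric(1))
  expect_true(all(diff(l1s) < 0))
  expect_equal(l1s[1], 1, tolerance = 1e-9)
})

test_that("masking marks the exact count uniformly and never empties a row or column", {
  x <- rand_expr(100, 10, seed = 23)
  expect_identical(mask_entries(x, 0), x)
  xm <- mask_entries(x, 0.1, seed = 1)
  expect_identical(sum(is.na(xm)), 100L)
  expect_identical(xm[!is.na(xm)], x[!is.na(xm)])

  for (s in 1:5) {
    y <- mask_entries(rand_expr(12, 6, seed = s), 0.4, seed = s)
    expect_true(all(rowSums(!is.na(y)) >= 1))
    expect_true(all(colSums(!is.na(y)) >= 1))
    expect_identical(sum(is.na(y)), as.integer(floor(0.4 * 72)))
  }
  expect_error(mask_entries(x, 1), "fraction")
  expect_identical(mask_entries(x, 0.2, seed = 9), mask_entries(x, 0.2, seed = 9))
})
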