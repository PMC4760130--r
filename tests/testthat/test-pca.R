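test_that("a perfectly anti-correlated gene pair is explained entirely by PC1", {
  x <- matrix(c(2, -2, -2, 2), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  f <- fit_pc1(x, mode = "standard")
  expect_equal(f$L1, 1.0, tolerance = 1e-12)
  expect_equal(abs(unname(f$loadings)), rep(1 / sqrt(2), 2), tolerance = 1e-9)
  expect_equal(sum(f$loadings), 0, tolerance = 1e-9)
})

test_that("uniform weight rescaling leaves the fit unchanged", {
  x <- rand_expr(12, 8, seed = 21)
  f1 <- fit_pc1(x, weights = rep(1, 12), seed = 3)
  f2 <- fit_pc1(x, weights = rep(7.3, 12), seed = 3)
  expect_equal(f1$loadings, f2$loadings, tolerance = 1e-10)
  expect_equal(f1$activity, f2$activity, tolerance = 1e-10)
  expect_equal(f1$L1, f2$L1, tolerance = 1e-10)
  expect_equal(f1$L2, f2$L2, tolerance = 1e-10)
})

test_that("iterative engine matches the dense eigensolver across modes and weights", {
  worst <- 0
  for (r in 1:30) {
    cfg <- withr::with_seed(100 + r, list(
      ng = sample(3:40, 1), ns = sample(3:25, 1),
      weighted = r %% 2 == 0, fixed = r %% 3 == 0))
    x <- rand_expr(cfg$ng, cfg$ns, seed = 200 + r)
    w <- if (cfg$weighted) withr::with_seed(300 + r, runif(cfg$ng, 0.2, 3)) else rep(1, cfg$ng)
    mode <- if (cfg$fixed) "fixed_center" else "standard"
    ctr <- if (cfg$fixed) withr::with_seed(400 + r, rnorm(cfg$ns, sd = 0.3)) else NULL
    f <- fit_pc1(x, weights = w, mode = mode, center = ctr, seed = 1)
    o <- eigen_l1l2(x, w, mode, ctr)
    worst <- max(worst, abs(f$L1 - o["L1"]), abs(f$L2 - o["L2"]))
  }
  expect_lt(worst, 1e-8)
})

test_that("fit invariants: unit loadings, zero-sum loadings, ordered variance fractions", {
  for (r in 1:10) {
    x <- rand_expr(15, 9, seed = 500 + r)
    f <- fit_pc1(x, mode = "standard", seed = r)
    expect_equal(sum(f$loadings^2), 1, tolerance = 1e-9)
    expect_equal(sum(f$loadings), 0, tolerance = 1e-7)
    expect_true(f$L2 >= 0 && f$L2 <= f$L1 && f$L1 <= 1)
    expect_lte(f$L1 + f$L2, 1 + 1e-9)
  }
  # fixed-center mode does not impose the zero-sum constraint
  xs <- rand_expr(10, 6, seed = 600) + 2
  fc <- fit_pc1(xs, mode = "fixed_center", center = rep(0, 6), seed = 1)
  expect_equal(sum(fc$loadings^2), 1, tolerance = 1e-9)
  expect_gt(abs(sum(fc$loadings)), 0.5)  # shifted set: loadings share a sign
})

test_that("permuting rows or columns permutes the fit without changing L1 and L2", {
  x <- rand_expr(14, 10, seed = 31)
  f <- fit_pc1(x, seed = 2)
  pg <- withr::with_seed(32, sample(nrow(x)))
  ps <- withr::with_seed(33, sample(ncol(x)))
  fp <- fit_pc1(x[pg, ps], seed = 2)
  expect_equal(fp$L1, f$L1, tolerance = 1e-10)
  expect_equal(fp$L2, f$L2, tolerance = 1e-10)
  s <- sign(sum(fp$loadings * f$loadings[pg]))
  expect_equal(s * fp$loadings, f$loadings[pg], tolerance = 1e-6)
  expect_equal(s * fp$activity, f$activity[ps], tolerance = 1e-6)
})

test_that("different initialization seeds converge to the same component", {
  x <- rand_expr(20, 12, seed = 41)
  f1 <- fit_pc1(x, seed = 0)
  f2 <- fit_pc1(x, seed = 987)
  expect_equal(abs(sum(f1$loadings * f2$loadings)), 1, tolerance = 1e-6)
})

test_that("degenerate zero-variance submatrices are rejected", {
  x <- matrix(5, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_error(fit_pc1(x, mode = "standard"), "degenerate")
  expect_error(fit_pc1(rand_expr(1, 5, 1)), "at least 2")
})

test_that("orientation follows signed weights, is involutive, and falls back to the module mean", {
  x <- rand_expr(6, 8, seed = 51)
  mod <- make_module("M", rownames(x),
                     weights = c(1, -1, 1, 1, 1, 1),
                     sign_defined = c(TRUE, TRUE, rep(FALSE, 4)))
  f <- fit_pc1(x, weights = abs(mod$genes$weight), seed = 1)

  s <- sum(mod$genes$weight[1:2] * f$loadings[1:2])
  o <- orient_pc1(f, mod, x_mod = x)
  expect_gte(sum(mod$genes$weight[1:2] * o$loadings[1:2]), 0)
  if (s < 0) {
    expect_equal(o$loadings, -f$loadings)
    expect_equal(o$activity, -f$activity)
  } else {
    expect_equal(o$loadings, f$loadings)
  }
  # PC2 projection never flips with component 1
  expect_equal(o$pc2_proj, f$pc2_proj)
  # involution: orienting twice equals orienting once
  expect_equal(orient_pc1(o, mod, x_mod = x), o)

  # negating every module sign negates the oriented activity exactly
  mod_neg <- mod
  mod_neg$genes$weight <- -mod$genes$weight
  o_neg <- orient_pc1(f, mod_neg, x_mod = x)
  expect_equal(o_neg$activity, -o$activity)
  expect_equal(o_neg$loadings, -o$loadings)

  # no signed genes: orient against the per-sample module mean
  mod_u <- make_module("U", rownames(x))
  fu <- orient_pc1(f, mod_u, x_mod = x)
  r <- cor(fu$activity, colMeans(x))
  expect_gte(r, 0)
  flipped <- f
  flipped$loadings <- -f$loadings
  flipped$activity <- -f$activity
  expect_equal(orient_pc1(flipped, mod_u, x_mod = x)$activity, fu$activity)
})

test_that("leave-one-out filtering removes a single high-amplitude aberrant gene at z_max 3", {
  x <- aberrant_fixture()
  rf <- robust_filter(x, z_max = 3.0)
  expect_identical(rf$report$removed_genes, "ABERRANT")
  expect_identical(rownames(x)[rf$retained], paste0("g", 1:20))
  # the default threshold is 3
  expect_identical(formals(robust_filter)$z_max, 3.0)
  # direct inspection: with the 100x gene present PC1 is captured by it, so
  # every other leave-one-out L1 stays near 1 and dropping the aberrant gene
  # gives the one outlying (lower) L1 value
  loo <- rf$report$loo_L1
  expect_identical(names(which.max(abs(rf$report$z_values))), "ABERRANT")
  expect_lt(loo["ABERRANT"], min(loo[names(loo) != "ABERRANT"]))
})

test_that("leave-one-out filtering limits: infinite threshold, degenerate spread, tiny modules", {
  x <- aberrant_fixture()
  expect_identical(robust_filter(x, z_max = Inf)$retained, seq_len(21L))

  const_loo <- matrix(rep(c(3, -3), 6), 4, 3, byrow = TRUE,
                      dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  rf0 <- robust_filter(const_loo, z_max = 3)
  expect_length(rf0$report$removed_genes, 0L)

  xs <- rand_expr(2, 5, seed = 61)
  expect_warning(rf2 <- robust_filter(xs), "at least 3")
  expect_identical(rf2$retained, 1:2)
})
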