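# Iterative SVD engine: rank-1/rank-2 fits of a module-restricted expression
# matrix under the uni-factor linear model
#   Expression(g, s) ~ alpha_g * Activity_s + B_s,
# minimizing sum_g |w_g| sum_s residual^2.

# One component by alternating least squares (power iteration).
# `m` is the residual matrix (already centered / deflated); weights enter the
# activity update and the objective; alpha is normalized in the unweighted
# Euclidean norm. In standard mode alpha is re-centered each iteration with
# the weight-weighted mean: because the columns of `m` have weighted mean
# zero, this is a no-op at the fixed point (and the printed zero-sum
# constraint for uniform weights), but it prevents drift along the constant
# direction during the iterations.
fit_component <- function(m, w, standard, seed, tol, max_iter) {
  ns <- ncol(m)
  a_s <- withr::with_seed(seed, rnorm(ns))
  alpha <- rep(0, nrow(m))
  n_iter <- max_iter
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    alpha_new <- as.vector(m %*% a_s) / sum(a_s^2)
    if (standard) alpha_new <- alpha_new - sum(w * alpha_new) / sum(w)
    nrm <- sqrt(sum(alpha_new^2))
    if (nrm < .Machine$double.eps) {
      # residual orthogonal to current activity: restart from a fresh vector
      a_s <- withr::with_seed(derive_seed(seed, iter), rnorm(ns))
      next
    }
    alpha_new <- alpha_new / nrm
    a_s <- as.vector(crossprod(m, w * alpha_new)) / sum(w * alpha_new^2)
    delta <- sqrt(sum((alpha_new - alpha)^2))
    alpha <- alpha_new
    if (delta < tol) {
      n_iter <- iter
      converged <- TRUE
      break
    }
  }
  list(alpha = alpha, activity = a_s, n_iter = n_iter, converged = converged)
}

#' Fit the first (and second) principal component of a module submatrix
#'
#' Computes the rank-1 fit `x[g, s] ~ alpha_g * Activity_s + B_s` by the
#' iterative SVD algorithm: starting from a seeded random activity vector,
#' alternate the loading update `alpha_g <- sum_s X'_gs A_s / sum_s A_s^2`
#' (with unit-norm renormalization, and zero-sum re-centering in standard
#' mode) and the weighted activity update
#' `A_s <- sum_g |w_g| alpha_g X'_gs / sum_g |w_g| alpha_g^2`, until the
#' loading vector changes by less than `tol`. In `standard` mode `B_s` is the
#' weighted per-sample mean over module genes; in `fixed_center` mode the
#' component is forced through the supplied global center `C_s` instead, so
#' gene sets displaced from the bulk of the data score high activity and the
#' zero-sum loading constraint is not imposed. The second component is fitted
#' identically on the deflated residual.
#'
#' @param x Complete numeric module-restricted matrix (genes x samples),
#'   at least 2 x 2; rows are assumed centered upstream for standard use.
#' @param weights Per-gene weight magnitudes (absolute values are used);
#'   default all 1.
#' @param mode `"standard"` or `"fixed_center"`.
#' @param center Per-sample global center vector, required in
#'   `"fixed_center"` mode (see [global_center()]).
#' @param seed Integer seed for the random activity initialization.
#' @param tol Convergence threshold on the Euclidean change of the loading
#'   vector between iterations.
#' @param max_iter Iteration cap; non-convergence warns and returns the best
#'   iterate.
#' @param rank 1 to fit only PC1 (cheaper, e.g. inside leave-one-out
#'   filtering), 2 to also fit PC2 on the deflated matrix.
#' @return An object of class `roma_pc1`: `loadings` (unit-norm, named by
#'   gene), `activity` (named by sample), `intercept` (`B_s`, or the fixed
#'   center used), `L1` and `L2` (fractions of the weighted module variance
#'   explained by components 1 and 2), `pc2_proj` (per-gene loading on
#'   component 2), `mode`, `n_iter`, `converged`.
#' @export
#' @examples
#' x <- matrix(c(2, -2, -2, 2), 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' f <- fit_pc1(x)
#' f$L1  # 1: a perfectly anti-correlated pair is rank one
fit_pc1 <- function(x, weights = NULL, mode = c("standard", "fixed_center"),
                    center = NULL, seed = 0L, tol = 1e-9, max_iter = 10000L,
                    rank = 2L) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(x), rank %in% c(1L, 2L))
  if (nrow(x) < 2L || ncol(x) < 2L) stop("fit_pc1 needs at least 2 genes and 2 samples")
  if (anyNA(x)) stop("fit_pc1 requires a complete submatrix; impute missing values first")
  if (is.null(weights)) weights <- rep(1, nrow(x))
  w <- abs(as.numeric(weights))
  if (length(w) != nrow(x) || any(w == 0) || any(!is.finite(w))) {
    stop("weights must be one finite non-zero value per gene")
  }

  standard <- mode == "standard"
  if (standard) {
    b <- as.vector(crossprod(x, w)) / sum(w)
  } else {
    if (is.null(center)) stop("fixed_center mode requires a global center vector")
    if (length(center) != ncol(x)) stop("center length must equal the number of samples")
    b <- as.numeric(center)
  }
  xp <- x - rep(b, each = nrow(x))
  tot <- sum(w * xp^2)
  if (tot <= 0) stop("degenerate module: zero weighted variance about the center")

  c1 <- fit_component(xp, w, standard, seed, tol, max_iter)
  if (!c1$converged) {
    warning("PC1 iteration did not converge in ", max_iter,
            " iterations; returning best iterate")
  }
  resid1 <- xp - tcrossprod(c1$alpha, c1$activity)
  l1 <- min(max(1 - sum(w * resid1^2) / tot, 0), 1)

  l2 <- 0
  pc2 <- rep(0, nrow(x))
  if (rank == 2L) {
    if (sum(w * resid1^2) > tot * 1e-14) {
      c2 <- fit_component(resid1, w, standard, derive_seed(seed, 2L), tol, max_iter)
      resid2 <- resid1 - tcrossprod(c2$alpha, c2$activity)
      l2 <- min(max((sum(w * resid1^2) - sum(w * resid2^2)) / tot, 0), l1)
      pc2 <- c2$alpha
    }
  }

  structure(list(
    loadings = stats::setNames(c1$alpha, rownames(x)),
    activity = stats::setNames(c1$activity, colnames(x)),
    intercept = stats::setNames(b, colnames(x)),
    L1 = l1, L2 = l2,
    pc2_proj = stats::setNames(pc2, rownames(x)),
    mode = mode, n_iter = c1$n_iter, converged = c1$converged
  ), class = "roma_pc1")
}

#' @export
print.roma_pc1 <- function(x, ...) {
  cat("PC1 fit (", x$mode, " mode): ", length(x$loadings), " genes x ",
      length(x$activity), " samples\n", sep = "")
  cat(sprintf("  L1 = %.4f, L2 = %.4f, L1/L2 = %s, iterations = %d\n",
              x$L1, x$L2,
              if (x$L2 > 0) sprintf("%.2f", x$L1 / x$L2) else "Inf",
              x$n_iter))
  invisible(x)
}

#' Orient a fitted first principal component
#'
#' PC1 is defined up to a global sign. When the module annotates some genes
#' with signed weights (activators positive, inhibitors negative), the
#' orientation is chosen so that `sum over signed genes of w_g * alpha_g > 0`.
#' When no gene has a defined sign (or the sum is exactly zero), the fallback
#' orients the activity to correlate non-negatively with the per-sample mean
#' expression of the module submatrix; a zero correlation leaves the fit as
#' computed.
#'
#' Negation flips `loadings` and `activity` (component 1 only); the PC2
#' projection is left untouched.
#'
#' @param fit A `roma_pc1` object fitted on the module's retained genes.
#' @param module A `roma_module` whose signed genes drive the orientation.
#' @param x_mod Optional module submatrix (same rows as the fit), used only
#'   for the no-signed-genes fallback.
#' @param verbose Emit a message when the orientation is left undetermined.
#' @return The fit, possibly with `loadings` and `activity` negated.
#' @export
orient_pc1 <- function(fit, module, x_mod = NULL, verbose = FALSE) {
  stopifnot(inherits(fit, "roma_pc1"), inherits(module, "roma_module"))
  g <- module$genes
  signed <- g[g$sign_defined & g$gene %in% names(fit$loadings), , drop = FALSE]
  s <- if (nrow(signed)) sum(signed$weight * fit$loadings[signed$gene]) else 0

  flip <- FALSE
  if (s < 0) {
    flip <- TRUE
  } else if (s == 0) {
    if (!is.null(x_mod)) {
      r <- suppressWarnings(cor(fit$activity, colMeans(x_mod)))
      if (!is.na(r) && r < 0) flip <- TRUE
      if (is.na(r) || r == 0) {
        roma_log("orientation of module '", module$name,
                 "' undetermined; leaving as computed", verbose = verbose)
      }
    } else {
      roma_log("no signed genes and no submatrix given; module '",
               module$name, "' left as computed", verbose = verbose)
    }
  }
  if (flip) {
    fit$loadings <- -fit$loadings
    fit$activity <- -fit$activity
  }
  fit
}

#' Leave-one-out outlier filtering of module genes
#'
#' A single aberrant gene can capture PC1 entirely. For each gene i, the PC1
#' explained-variance fraction `L1^i` is recomputed with gene i left out; the
#' `L1^i` values are converted to z-scores (sample standard deviation), and
#' all genes with `|z| > z_max` are removed in a single pass. If the L1
#' distribution is degenerate (zero spread), or fewer than 3 genes are
#' available, nothing is removed.
#'
#' @param x Complete module submatrix (genes x samples).
#' @param weights Per-gene weight magnitudes; default all 1.
#' @param mode,center,seed,tol,max_iter Passed to [fit_pc1()].
#' @param z_max Removal threshold on `|z|` (default 3).
#' @return A list with `retained` (integer indices of kept genes) and
#'   `report`, itself a list with `removed_genes`, `loo_L1`, `z_values`
#'   and `z_max`.
#' @export
robust_filter <- function(x, weights = NULL, mode = c("standard", "fixed_center"),
                          center = NULL, z_max = 3.0, seed = 0L,
                          tol = 1e-9, max_iter = 10000L) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(x), z_max > 0)
  n <- nrow(x)
  if (is.null(weights)) weights <- rep(1, n)
  empty_report <- list(removed_genes = character(0),
                       loo_L1 = numeric(0), z_values = numeric(0), z_max = z_max)
  if (n < 3L) {
    warning("robust_filter needs at least 3 genes; skipping filtering")
    return(list(retained = seq_len(n), report = empty_report))
  }

  loo <- vapply(seq_len(n), function(i) {
    tryCatch(
      suppressWarnings(
        fit_pc1(x[-i, , drop = FALSE], weights = weights[-i], mode = mode,
                center = center, seed = seed, tol = tol, max_iter = max_iter,
                rank = 1L)$L1
      ),
      error = function(e) NA_real_
    )
  }, numeric(1L))

  mu <- mean(loo, na.rm = TRUE)
  sdev <- sd(loo, na.rm = TRUE)
  z <- if (is.na(sdev) || sdev == 0) rep(0, n) else (loo - mu) / sdev
  z[is.na(z)] <- 0
  removed <- abs(z) > z_max
  if (n - sum(removed) < 2L) {
    warning("outlier removal would leave fewer than 2 genes; keeping all genes")
    removed[] <- FALSE
  }
  report <- list(
    removed_genes = rownames(x)[removed],
    loo_L1 = stats::setNames(loo, rownames(x)),
    z_values = stats::setNames(z, rownames(x)),
    z_max = z_max
  )
  list(retained = which(!removed), report = report)
}
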