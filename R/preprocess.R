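#' Center each gene row at zero
#'
#' Subtracts from every gene its mean over observed (non-missing) entries, so
#' that each row sums to zero. Row centering removes basal expression level,
#' without which PC1 tends to capture differences in baseline rather than
#' coordinated variation across samples.
#'
#' @param x Numeric genes-by-samples matrix; `NA` entries allowed.
#' @return Matrix of the same shape and dimnames, rows centered over
#'   observed entries.
#' @export
center_rows <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 1L)
  n_obs <- rowSums(!is.na(x))
  if (any(n_obs == 0L)) {
    stop("gene(s) with no observed entries: ",
         paste(rownames(x)[n_obs == 0L], collapse = ", "))
  }
  x - rowMeans(x, na.rm = TRUE)
}

#' Double-center a complete expression matrix
#'
#' Makes every row sum and every column sum zero by subtracting row means and
#' column means and adding back the grand mean. Requires a complete matrix
#' (impute first). Double-centering additionally removes the per-sample bias
#' term, but cannot hold simultaneously for all gene subsets, so it is
#' optional in the pipeline.
#'
#' @param x Complete numeric matrix.
#' @return Double-centered matrix of the same shape and dimnames.
#' @export
double_center <- function(x) {
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("double_center requires a complete matrix; impute missing values first")
  x - rowMeans(x) - rep(colMeans(x), each = nrow(x)) + mean(x)
}

#' Global center of the data distribution
#'
#' Per-sample mean over all dataset genes (not module-restricted). This is the
#' fixed point through which fixed-center PC1 fits are constrained to pass,
#' so that gene sets shifted away from the bulk of the data — not only
#' overdispersed ones — score high activity.
#'
#' @param x Complete numeric genes-by-samples matrix.
#' @return Numeric vector of length `ncol(x)`, named by sample.
#' @export
global_center <- function(x) {
  stopifnot(is.matrix(x), nrow(x) >= 1L, ncol(x) >= 1L)
  if (anyNA(x)) stop("global_center requires a complete matrix")
  colMeans(x)
}

#' Impute missing values by low-rank approximation
#'
#' Fits the model `x[g, s] ~ B_s + sum_k alpha[g, k] * A[s, k]` with
#' `k_rank` components by alternating least squares in which every sum runs
#' over observed entries only — the same update structure as the iterative
#' SVD used for PC1 fitting — and replaces each missing entry by the fitted
#' reconstruction. Observed entries are returned unchanged.
#'
#' @param x Numeric matrix with `NA` marking missing entries.
#' @param k_rank Rank of the approximating complete matrix,
#'   `1 <= k_rank < min(dim(x))`.
#' @param tol Convergence threshold on the relative Frobenius change of the
#'   reconstruction between sweeps.
#' @param max_iter Maximum number of sweeps; non-convergence warns and
#'   returns the current estimate.
#' @param seed Integer seed for the random initialization of component
#'   activities.
#' @return Complete matrix: observed entries exactly as in `x`, missing
#'   entries imputed.
#' @export
impute_missing <- function(x, k_rank, tol = 1e-8, max_iter = 1000L, seed = 0L) {
  stopifnot(is.matrix(x), k_rank >= 1L)
  if (k_rank >= min(dim(x))) stop("k_rank must be smaller than both matrix dimensions")
  obs <- !is.na(x)
  if (!anyNA(x)) return(x)
  if (any(rowSums(obs) == 0L)) {
    stop("fully missing gene row(s): ", paste(rownames(x)[rowSums(obs) == 0L], collapse = ", "))
  }
  if (any(colSums(obs) == 0L)) {
    stop("fully missing sample column(s): ", paste(colnames(x)[colSums(obs) == 0L], collapse = ", "))
  }

  ng <- nrow(x); ns <- ncol(x)
  x0 <- x; x0[!obs] <- 0
  alpha <- matrix(0, ng, k_rank)
  act <- withr::with_seed(seed, matrix(rnorm(ns * k_rank), ns, k_rank))
  b <- colSums(x0) / colSums(obs)

  recon <- function() rep(b, each = ng) + alpha %*% t(act)
  prev <- recon()
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    fit_k <- alpha %*% t(act)
    b <- colSums((x0 - fit_k) * obs) / colSums(obs)
    resid <- (x0 - rep(b, each = ng) - fit_k) * obs
    for (k in seq_len(k_rank)) {
      # residual with component k added back in
      rk <- resid + tcrossprod(alpha[, k], act[, k]) * obs
      den_a <- obs %*% act[, k]^2
      a_new <- as.vector((rk %*% act[, k]) / pmax(den_a, .Machine$double.eps))
      nrm <- sqrt(sum(a_new^2))
      if (nrm > 0) a_new <- a_new / nrm
      den_s <- crossprod(obs, a_new^2)
      s_new <- as.vector(crossprod(rk, a_new) / pmax(den_s, .Machine$double.eps))
      alpha[, k] <- a_new
      act[, k] <- s_new
      resid <- rk - tcrossprod(a_new, s_new) * obs
    }
    cur <- recon()
    delta <- sqrt(sum((cur - prev)^2)) / max(sqrt(sum(prev^2)), .Machine$double.eps)
    prev <- cur
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("impute_missing did not converge in ", max_iter, " sweeps; returning current estimate")
  }
  out <- x
  out[!obs] <- prev[!obs]
  out
}
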