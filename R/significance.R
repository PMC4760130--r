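# Empirical significance of module overdispersion (L1) and coordination
# (L1/L2) against random gene sets. The randomly expected L1 depends strongly
# on set size, so nulls are built on a log-scale grid of sizes and each
# module is compared to the grid size nearest in log scale.

#' Log-scale grid of gene-set sizes for null distributions
#'
#' Returns sizes spaced uniformly in log scale between the smallest and the
#' largest module size in a collection, rounded to integers, deduplicated and
#' clamped to the range. Both endpoints are always included.
#'
#' @param min_size,max_size Smallest and largest module size (2 <= min <= max).
#' @param n_grid Number of grid points before deduplication.
#' @return Sorted unique integer vector of sizes.
#' @export
#' @examples
#' build_size_grid(10, 1000, 3)  # 10, 100, 1000
build_size_grid <- function(min_size, max_size, n_grid = 10L) {
  stopifnot(n_grid >= 1L)
  if (min_size > max_size) stop("min_size must not exceed max_size")
  if (min_size < 2L) stop("gene-set sizes below 2 cannot be scored")
  if (min_size == max_size) return(as.integer(min_size))
  pts <- exp(seq(log(min_size), log(max_size), length.out = n_grid))
  sizes <- pmin(pmax(round(pts), min_size), max_size)
  sort(unique(as.integer(sizes)))
}

#' Sample the null distribution of L1 and L1/L2 for one gene-set size
#'
#' Draws `K` gene sets of the given size uniformly without replacement from
#' all dataset genes, fits PC1/PC2 to each (unit weights, no outlier
#' filtering — a random set carries no prior structure) with the same mode
#' and center as the real modules, and records the explained-variance
#' fraction L1 and the ratio L1/L2.
#'
#' @param x Complete preprocessed genes-by-samples matrix.
#' @param size Gene-set size; must not exceed `nrow(x)`.
#' @param K Number of random sets.
#' @param mode,center,pca_seed,tol,max_iter Passed to [fit_pc1()].
#' @param seed Seed for the random gene draws; the same seed reproduces the
#'   same samples exactly.
#' @return An object of class `roma_null`: list with `size`, `l1` (K values
#'   in `[0, 1]`) and `ratio` (K values >= 1).
#' @export
sample_null <- function(x, size, K, mode = c("standard", "fixed_center"),
                        center = NULL, seed = 0L, pca_seed = 0L,
                        tol = 1e-9, max_iter = 10000L) {
  mode <- match.arg(mode)
  stopifnot(K >= 1L)
  if (size > nrow(x)) stop("null set size ", size, " exceeds gene count ", nrow(x))
  if (size < 2L) stop("null set size must be at least 2")

  idx <- withr::with_seed(seed,
    replicate(K, sample.int(nrow(x), size), simplify = FALSE))
  l1 <- numeric(K)
  ratio <- numeric(K)
  for (k in seq_len(K)) {
    f <- suppressWarnings(fit_pc1(x[idx[[k]], , drop = FALSE], mode = mode,
                                  center = center, seed = pca_seed,
                                  tol = tol, max_iter = max_iter, rank = 2L))
    l1[k] <- f$L1
    ratio[k] <- if (f$L2 > 0) f$L1 / f$L2 else Inf
  }
  structure(list(size = as.integer(size), l1 = l1, ratio = ratio),
            class = "roma_null")
}

#' Add-one empirical p-value
#'
#' `p = (1 + #null >= observed) / (K + 1)`, the permutation-test convention:
#' the observed value counts as one more draw from the null, so p is never 0
#' and its attainable minimum is `1/(K+1)`.
#'
#' @param observed Observed statistic (`Inf` is allowed for a degenerate
#'   L1/L2 with a zero second component).
#' @param null_samples Vector of K null statistics.
#' @return p-value in `[1/(K+1), 1]`.
#' @export
empirical_pvalue <- function(observed, null_samples) {
  if (length(null_samples) == 0L) stop("empty null distribution")
  if (is.na(observed)) stop("observed statistic must not be NA")
  (1 + sum(null_samples >= observed)) / (length(null_samples) + 1)
}

#' Pick the null distribution closest in log-scale size
#'
#' @param size Effective size of the tested module.
#' @param nulls Named or unnamed list of `roma_null` objects.
#' @return The `roma_null` whose size minimizes `|log(size) - log(grid)|`;
#'   ties break toward the smaller grid size.
#' @export
nearest_null <- function(size, nulls) {
  if (length(nulls) == 0L) stop("no null distributions available")
  sizes <- vapply(nulls, `[[`, integer(1L), "size")
  d <- abs(log(size) - log(sizes))
  # candidates within float tolerance of the minimum, so exact log-midpoint
  # ties resolve to the smaller grid size regardless of rounding direction
  cand <- which(d <= min(d) + 1e-12)
  nulls[[cand[which.min(sizes[cand])]]]
}
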