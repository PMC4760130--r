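# Synthetic expression data with planted hidden factors. The generator
# instantiates the same uni-factor linear model the PC1 fit inverts, so
# estimated loadings and activities can be checked against known truth.

#' Specification of one planted module
#'
#' Describes a gene set whose expression is driven by `n_factors` hidden
#' factors plus Gaussian noise. Factor 1 uses the supplied loadings and
#' activity; factors 2..n (the "overdispersed but not coordinated" case) get
#' seeded random unit loadings and activities with the same standard
#' deviation as factor 1.
#'
#' @param name Module name (unique across specs).
#' @param true_loadings Numeric vector of per-gene response coefficients;
#'   normalized internally to unit Euclidean norm. Length >= 2.
#' @param true_activity Numeric vector of per-sample factor activities.
#' @param noise_sd Standard deviation of the additive Gaussian noise (>= 0).
#' @param n_factors Number of independent hidden factors (>= 1).
#' @return A list of class `planted_module_spec`.
#' @export
planted_module_spec <- function(name, true_loadings, true_activity,
                                noise_sd = 0.5, n_factors = 1L) {
  stopifnot(length(true_loadings) >= 2L, noise_sd >= 0, n_factors >= 1L)
  nrm <- sqrt(sum(true_loadings^2))
  if (nrm == 0) stop("true_loadings must not be all zero")
  structure(list(
    name = name,
    true_loadings = true_loadings / nrm,
    true_activity = as.numeric(true_activity),
    noise_sd = noise_sd,
    n_factors = as.integer(n_factors)
  ), class = "planted_module_spec")
}

#' Generate an expression matrix with planted factor-driven modules
#'
#' Background genes are iid Gaussian noise. Each planted gene g in a spec is
#' `sum_k alpha_g^(k) * A_s^(k) + N(0, noise_sd^2)`; all rows are then
#' row-centered, matching the model's normalization. Module definitions are
#' emitted for every planted set (with signed weights from the loading signs,
#' to exercise orientation) and, optionally, for random control sets drawn
#' from the background genes. Fully reproducible for a fixed seed.
#'
#' @param n_background_genes Number of pure-noise genes.
#' @param n_samples Number of samples (>= 3).
#' @param specs List of [planted_module_spec()] objects (may be empty).
#' @param background_sd Standard deviation of background gene expression.
#' @param seed Integer seed.
#' @param n_control_sets,control_size Number and size of random control
#'   module definitions drawn from background genes (unsigned, weight 1).
#' @param signed_weights Emit planted-module GMT weights as the sign of the
#'   true loadings (`TRUE`, default) or as unsigned 1.0 (`FALSE`).
#' @return A list with `x` (the row-centered matrix, planted genes named
#'   `<module>_g<i>`, background genes `BG<i>`), `modules` (list of
#'   `roma_module`), and `truth` — per planted module the loading matrix
#'   (genes x factors) and activity matrix (samples x factors) actually used.
#' @export
simulate_expression <- function(n_background_genes, n_samples, specs = list(),
                                background_sd = 1.0, seed = 0L,
                                n_control_sets = 0L, control_size = 10L,
                                signed_weights = TRUE) {
  stopifnot(n_samples >= 3L, n_background_genes >= 0L)
  if (inherits(specs, "planted_module_spec")) specs <- list(specs)
  spec_names <- vapply(specs, `[[`, character(1L), "name")
  if (anyDuplicated(spec_names)) {
    stop("duplicate planted module name: ",
         paste(unique(spec_names[duplicated(spec_names)]), collapse = ", "))
  }
  for (sp in specs) {
    if (length(sp$true_activity) != n_samples) {
      stop("spec '", sp$name, "': true_activity length must equal n_samples")
    }
  }

  withr::with_seed(seed, {
    sample_ids <- paste0("S", seq_len(n_samples))
    blocks <- list()
    truth <- list()
    modules <- list()

    for (sp in specs) {
      ng <- length(sp$true_loadings)
      load_mat <- matrix(0, ng, sp$n_factors)
      act_mat <- matrix(0, n_samples, sp$n_factors)
      load_mat[, 1L] <- sp$true_loadings
      act_mat[, 1L] <- sp$true_activity
      if (sp$n_factors > 1L) {
        a1_sd <- sd(sp$true_activity)
        for (k in 2:sp$n_factors) {
          v <- rnorm(ng)
          load_mat[, k] <- v / sqrt(sum(v^2))
          # equally strong independent factor: centered, rescaled so its
          # empirical sd equals factor 1's exactly
          a <- rnorm(n_samples)
          act_mat[, k] <- (a - mean(a)) / sd(a) * a1_sd
        }
      }
      signal <- load_mat %*% t(act_mat)
      noise <- matrix(rnorm(ng * n_samples, sd = sp$noise_sd), ng, n_samples)
      gene_ids <- paste0(sp$name, "_g", seq_len(ng))
      block <- signal + noise
      dimnames(block) <- list(gene_ids, sample_ids)
      blocks[[sp$name]] <- block
      rownames(load_mat) <- gene_ids
      truth[[sp$name]] <- list(loadings = load_mat, activity = act_mat)

      w <- if (signed_weights) sign(sp$true_loadings) else rep(1, ng)
      w[w == 0] <- 1
      modules[[sp$name]] <- structure(list(
        name = sp$name,
        description = paste0("planted ", sp$n_factors, "-factor module"),
        genes = data.frame(gene = gene_ids, weight = w,
                           sign_defined = rep(isTRUE(signed_weights), ng),
                           stringsAsFactors = FALSE)
      ), class = "roma_module")
    }

    bg <- NULL
    if (n_background_genes > 0L) {
      bg <- matrix(rnorm(n_background_genes * n_samples, sd = background_sd),
                   n_background_genes, n_samples,
                   dimnames = list(paste0("BG", seq_len(n_background_genes)),
                                   sample_ids))
    }
    x <- do.call(rbind, c(blocks, if (!is.null(bg)) list(bg)))
    x <- center_rows(x)

    if (n_control_sets > 0L) {
      if (is.null(bg)) stop("control sets need background genes")
      if (control_size > n_background_genes) {
        stop("control_size exceeds the number of background genes")
      }
      for (i in seq_len(n_control_sets)) {
        gs <- sample(rownames(bg), control_size)
        nm <- paste0("CONTROL", i)
        modules[[nm]] <- structure(list(
          name = nm, description = "random background control set",
          genes = data.frame(gene = gs, weight = rep(1, control_size),
                             sign_defined = rep(FALSE, control_size),
                             stringsAsFactors = FALSE)
        ), class = "roma_module")
      }
    }

    list(x = x, modules = modules, truth = truth)
  })
}

#' Mask a fraction of matrix entries as missing
#'
#' Marks `floor(fraction * length(x))` uniformly chosen entries as `NA`,
#' never emptying a whole row or column.
#'
#' @param x Numeric matrix.
#' @param fraction Fraction of cells to mask, in `[0, 1)`.
#' @param seed Integer seed.
#' @return The matrix with masked entries set to `NA`.
#' @export
mask_entries <- function(x, fraction, seed = 0L) {
  stopifnot(is.matrix(x))
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  m <- floor(fraction * length(x))
  if (m == 0L) return(x)

  withr::with_seed(seed, {
    order_cells <- sample.int(length(x))
    row_obs <- rep(ncol(x), nrow(x))
    col_obs <- rep(nrow(x), ncol(x))
    masked <- 0L
    out <- x
    for (cell in order_cells) {
      if (masked == m) break
      i <- ((cell - 1L) %% nrow(x)) + 1L
      j <- ((cell - 1L) %/% nrow(x)) + 1L
      if (row_obs[i] > 1L && col_obs[j] > 1L) {
        out[i, j] <- NA_real_
        row_obs[i] <- row_obs[i] - 1L
        col_obs[j] <- col_obs[j] - 1L
        masked <- masked + 1L
      }
    }
    if (masked < m) {
      stop("cannot mask ", m, " entries without emptying a row or column")
    }
    out
  })
}
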