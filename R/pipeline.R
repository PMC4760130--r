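#' Configuration for a ROMA run
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' the method's reference settings: fixed-center PCA, leave-one-out outlier
#' filtering at `z_max = 3`, modules scored only when at least 8 of their
#' genes are found in the dataset, and nulls of `K = 999` random sets on a
#' 10-point log-scale size grid (attainable minimum p-value 0.001).
#'
#' @param centering How the matrix is centered before scoring: `"rows"`
#'   (each gene centered over samples; the model's assumption), `"double"`
#'   (rows and columns; also removes the per-sample bias term) or `"none"`.
#' @param mode PC1 mode, `"fixed_center"` (default) or `"standard"`; see
#'   [fit_pc1()].
#' @param robust Logical: apply [robust_filter()] per module.
#' @param z_max Leave-one-out removal threshold.
#' @param min_module_size Minimum number of module genes matched in the
#'   dataset for the module to be scored (>= 2).
#' @param K Random gene sets per null distribution (>= 1).
#' @param n_grid Points of the log-scale size grid.
#' @param pca_seed Seed for PC1 initialization vectors.
#' @param null_seed Master seed for null gene-set draws; per-size streams are
#'   derived from it so adding grid sizes never changes existing nulls.
#' @param impute_k_rank Rank for missing-value imputation, or `NULL` if the
#'   matrix is complete.
#' @param impute_tol,impute_max_iter Imputation convergence controls.
#' @param tol,max_iter PC1 iteration controls.
#' @param verbose Emit progress messages.
#' @return A list of class `roma_config`.
#' @export
roma_config <- function(centering = c("rows", "double", "none"),
                        mode = c("fixed_center", "standard"),
                        robust = TRUE, z_max = 3.0,
                        min_module_size = 8L,
                        K = 999L, n_grid = 10L,
                        pca_seed = 0L, null_seed = 0L,
                        impute_k_rank = NULL,
                        impute_tol = 1e-8, impute_max_iter = 1000L,
                        tol = 1e-9, max_iter = 10000L,
                        verbose = FALSE) {
  centering <- match.arg(centering)
  mode <- match.arg(mode)
  stopifnot(min_module_size >= 2L, z_max > 0, K >= 1L, n_grid >= 1L)
  structure(list(
    centering = centering, mode = mode, robust = isTRUE(robust), z_max = z_max,
    min_module_size = as.integer(min_module_size),
    K = as.integer(K), n_grid = as.integer(n_grid),
    pca_seed = as.integer(pca_seed), null_seed = as.integer(null_seed),
    impute_k_rank = impute_k_rank,
    impute_tol = impute_tol, impute_max_iter = as.integer(impute_max_iter),
    tol = tol, max_iter = as.integer(max_iter), verbose = isTRUE(verbose)
  ), class = "roma_config")
}

#' Score a collection of modules on an expression matrix
#'
#' End-to-end workflow: impute missing values (when `impute_k_rank` is set),
#' center the matrix, compute the global center, then for each module match
#' its genes to the dataset, remove leave-one-out outliers, fit and orient
#' PC1, and assess the significance of the overdispersion score L1 and the
#' coordination score L1/L2 against empirical nulls of random gene sets of
#' the nearest (log-scale) size. Modules with fewer matched genes than
#' `min_module_size` are skipped with a logged reason. Deterministic for
#' fixed seeds.
#'
#' @param x Numeric genes-by-samples matrix (see [read_expression()]).
#' @param modules List of `roma_module` objects (see [read_gmt()]).
#' @param annotation Optional sample annotation data frame (unused by the
#'   scoring itself; carried through for downstream comparisons).
#' @param config A [roma_config()] list.
#' @return Object of class `roma_result`, a list with:
#'   `scores` — data frame with one row per scored module (`module`,
#'   `size_in_file`, `size_effective`, `L1`, `p_L1`, `L1_div_L2`,
#'   `p_L1_div_L2`, `n_outliers`, plus Benjamini-Hochberg adjusted columns
#'   `p_L1_BH` and `p_L1_div_L2_BH`); `activities` — modules x samples
#'   matrix of oriented activity scores; `projections` — named list of
#'   per-module gene tables; `fits` — the oriented `roma_pc1` objects;
#'   `nulls` — the null distributions keyed by grid size; `log` — per-module
#'   audit records (matched genes, outliers removed, iterations, null size
#'   used); `skipped` — named integer vector of match counts for skipped
#'   modules; `config` — the configuration used.
#' @export
run_roma <- function(x, modules, annotation = NULL, config = roma_config()) {
  stopifnot(is.matrix(x), length(modules) >= 1L)
  if (inherits(modules, "roma_module")) modules <- list(modules)
  cfg <- config

  if (anyNA(x)) {
    if (is.null(cfg$impute_k_rank)) {
      stop("expression matrix has missing values; set impute_k_rank in roma_config()")
    }
    roma_log("imputing missing values at rank ", cfg$impute_k_rank, verbose = cfg$verbose)
    x <- impute_missing(x, cfg$impute_k_rank, tol = cfg$impute_tol,
                        max_iter = cfg$impute_max_iter, seed = cfg$pca_seed)
  }
  x <- switch(cfg$centering,
              rows = center_rows(x),
              double = double_center(x),
              none = x)
  ctr <- global_center(x)
  use_center <- if (cfg$mode == "fixed_center") ctr else NULL

  matched <- lapply(modules, function(m) m$genes[m$genes$gene %in% rownames(x), , drop = FALSE])
  match_counts <- vapply(matched, nrow, integer(1L))
  names(match_counts) <- vapply(modules, `[[`, character(1L), "name")
  keep <- match_counts >= cfg$min_module_size
  if (!any(keep)) {
    stop("no module passes the size filter (min_module_size = ", cfg$min_module_size,
         "); matched counts: ",
         paste(names(match_counts), match_counts, sep = "=", collapse = ", "))
  }
  for (nm in names(match_counts)[!keep]) {
    roma_log("skipping module '", nm, "': ", match_counts[nm],
             " genes matched < min_module_size = ", cfg$min_module_size,
             verbose = cfg$verbose)
  }

  idx_keep <- which(keep)
  n_mod <- length(idx_keep)
  fits <- vector("list", n_mod)
  projections <- vector("list", n_mod)
  log_rows <- vector("list", n_mod)
  eff_size <- integer(n_mod)
  out_count <- integer(n_mod)
  mod_names <- names(match_counts)[idx_keep]

  for (j in seq_len(n_mod)) {
    m <- modules[[idx_keep[j]]]
    g <- matched[[idx_keep[j]]]
    x_mod <- x[g$gene, , drop = FALSE]
    w <- abs(g$weight)

    removed <- character(0)
    retained <- seq_len(nrow(g))
    if (cfg$robust && nrow(g) >= 3L) {
      rf <- robust_filter(x_mod, weights = w, mode = cfg$mode, center = use_center,
                          z_max = cfg$z_max, seed = cfg$pca_seed,
                          tol = cfg$tol, max_iter = cfg$max_iter)
      retained <- rf$retained
      removed <- rf$report$removed_genes
    }
    g_ret <- g[retained, , drop = FALSE]
    x_ret <- x_mod[retained, , drop = FALSE]

    fit <- fit_pc1(x_ret, weights = abs(g_ret$weight), mode = cfg$mode,
                   center = use_center, seed = cfg$pca_seed,
                   tol = cfg$tol, max_iter = cfg$max_iter, rank = 2L)
    fit <- orient_pc1(fit, m, x_mod = x_ret, verbose = cfg$verbose)

    proj <- data.frame(
      gene = g$gene,
      weight = g$weight,
      alpha_pc1 = NA_real_,
      proj_pc2 = NA_real_,
      is_outlier = g$gene %in% removed,
      stringsAsFactors = FALSE
    )
    proj$alpha_pc1[retained] <- fit$loadings
    proj$proj_pc2[retained] <- fit$pc2_proj

    fits[[j]] <- fit
    projections[[j]] <- proj
    eff_size[j] <- nrow(g_ret)
    out_count[j] <- length(removed)
    log_rows[[j]] <- data.frame(
      module = m$name, matched = nrow(g), retained = nrow(g_ret),
      outliers = paste(removed, collapse = ";"),
      n_iter = fit$n_iter, stringsAsFactors = FALSE
    )
  }
  names(fits) <- names(projections) <- mod_names

  grid <- build_size_grid(max(2L, min(eff_size)), max(eff_size), cfg$n_grid)
  nulls <- lapply(grid, function(s) {
    roma_log("sampling null for size ", s, " (K = ", cfg$K, ")", verbose = cfg$verbose)
    sample_null(x, s, cfg$K, mode = cfg$mode, center = use_center,
                seed = derive_seed(cfg$null_seed, s), pca_seed = cfg$pca_seed,
                tol = cfg$tol, max_iter = cfg$max_iter)
  })
  names(nulls) <- as.character(grid)

  l1 <- vapply(fits, `[[`, numeric(1L), "L1")
  l2 <- vapply(fits, `[[`, numeric(1L), "L2")
  ratio <- ifelse(l2 > 0, l1 / l2, Inf)
  p_l1 <- numeric(n_mod)
  p_ratio <- numeric(n_mod)
  null_used <- integer(n_mod)
  for (j in seq_len(n_mod)) {
    nd <- nearest_null(eff_size[j], nulls)
    null_used[j] <- nd$size
    p_l1[j] <- empirical_pvalue(l1[j], nd$l1)
    p_ratio[j] <- empirical_pvalue(ratio[j], nd$ratio)
    log_rows[[j]]$null_size <- nd$size
  }

  scores <- data.frame(
    module = mod_names,
    size_in_file = vapply(modules[idx_keep], function(m) nrow(m$genes), integer(1L)),
    size_effective = eff_size,
    L1 = l1,
    p_L1 = p_l1,
    L1_div_L2 = ratio,
    p_L1_div_L2 = p_ratio,
    n_outliers = out_count,
    p_L1_BH = p.adjust(p_l1, method = "BH"),
    p_L1_div_L2_BH = p.adjust(p_ratio, method = "BH"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )

  activities <- do.call(rbind, lapply(fits, `[[`, "activity"))
  rownames(activities) <- mod_names
  colnames(activities) <- colnames(x)

  structure(list(
    scores = scores,
    activities = activities,
    projections = projections,
    fits = fits,
    nulls = nulls,
    log = do.call(rbind, log_rows),
    skipped = match_counts[!keep],
    config = cfg
  ), class = "roma_result")
}

#' @export
print.roma_result <- function(x, ...) {
  cat("ROMA result: ", nrow(x$scores), " module(s) scored on ",
      ncol(x$activities), " samples (", length(x$skipped), " skipped)\n", sep = "")
  print(x$scores[, c("module", "size_effective", "L1", "p_L1",
                     "L1_div_L2", "p_L1_div_L2", "n_outliers")],
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' Compare module activities between two sample groups
#'
#' For each module, a two-sample two-sided Kolmogorov-Smirnov test (asymptotic
#' p-value) compares the activity scores of samples carrying `group_a` vs
#' `group_b` in annotation column `feature`.
#'
#' @param activities Modules x samples activity matrix (see [run_roma()] or
#'   [read_activities()]).
#' @param annotation Data frame with sample names as row names.
#' @param feature Annotation column holding the group labels.
#' @param group_a,group_b The two labels to compare; each needs >= 2 samples.
#' @return Data frame with columns `module`, `n_a`, `n_b`, `D`, `p_value`,
#'   sorted by p ascending.
#' @export
compare_groups <- function(activities, annotation, feature, group_a, group_b) {
  stopifnot(is.matrix(activities))
  if (!feature %in% colnames(annotation)) {
    stop("unknown annotation feature: ", feature)
  }
  labels <- stats::setNames(as.character(annotation[[feature]]), rownames(annotation))
  common <- intersect(colnames(activities), names(labels))
  a_ids <- common[labels[common] == group_a]
  b_ids <- common[labels[common] == group_b]
  if (length(a_ids) == 0L && length(b_ids) == 0L) {
    stop("labels '", group_a, "' and '", group_b, "' not found in feature '", feature, "'")
  }
  if (length(a_ids) < 2L || length(b_ids) < 2L) {
    stop("both groups need at least 2 samples (", group_a, ": ", length(a_ids),
         ", ", group_b, ": ", length(b_ids), ")")
  }
  res <- lapply(rownames(activities), function(m) {
    kt <- suppressWarnings(
      ks.test(activities[m, a_ids], activities[m, b_ids],
              alternative = "two.sided", exact = FALSE))
    data.frame(module = m, n_a = length(a_ids), n_b = length(b_ids),
               D = unname(kt$statistic), p_value = kt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p_value, out$module), , drop = FALSE]
  rownames(out) <- NULL
  out
}
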