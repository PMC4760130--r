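#' Read a tab-delimited expression matrix
#'
#' Parses the standard genes-by-samples layout: the first line holds sample
#' identifiers, the first column holds non-redundant gene (or protein) names,
#' remaining cells are numeric expression values. Values are used as provided
#' (a log-like scale is assumed but not enforced). The header line may or may
#' not carry a corner label above the gene-name column; both conventions are
#' accepted.
#'
#' @param path Path to the tab-delimited file.
#' @param na_tokens Character vector of cell values treated as missing.
#'   Missing cells become `NA` in the returned matrix.
#' @return A numeric matrix, rows named by gene, columns named by sample.
#'   Missing entries are `NA`; every non-missing entry is finite.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("S1\tS2", "TP53\t1.5\t2.0", "MDM2\t0.1\tNA"), tf)
#' x <- read_expression(tf)
#' dim(x)
read_expression <- function(path, na_tokens = c("NA", "NaN", "")) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (length(lines) < 2L) stop("expression file needs a header line and at least one gene row: ", path)

  fields <- split_tsv(lines)
  header <- fields[[1L]]
  body <- fields[-1L]

  n_body <- lengths(body)
  if (length(unique(n_body)) != 1L) {
    bad <- which(n_body != n_body[1L])[1L]
    stop("ragged row in expression file at line ", bad + 1L,
         ": expected ", n_body[1L], " fields, found ", n_body[bad])
  }
  n_fields <- n_body[1L]
  if (n_fields < 2L) stop("expression rows must contain a gene name and at least one value")

  if (length(header) == n_fields) {
    sample_ids <- header[-1L]          # corner label present
  } else if (length(header) == n_fields - 1L) {
    sample_ids <- header               # bare sample-ID header
  } else {
    stop("header has ", length(header), " fields but data rows have ", n_fields)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifier: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }

  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene name in expression file: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }

  cells <- matrix(unlist(lapply(body, `[`, -1L), use.names = FALSE),
                  nrow = length(body), byrow = TRUE)
  is_na <- matrix(cells %in% na_tokens, nrow = nrow(cells))
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- !is_na & (is.na(values) | !is.finite(values))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-numeric value '", cells[idx[1L], idx[2L]], "' at gene ",
         gene_ids[idx[1L]], ", sample ", sample_ids[idx[2L]])
  }
  values[is_na] <- NA_real_
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_expression()]: first line sample IDs (with a corner
#' label), first column gene names, `NA` for missing entries, numbers with
#' at least 6 significant digits.
#'
#' @param x Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param digits Significant digits to render (>= 6).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, digits = 7L) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)), digits >= 6L)
  header <- paste(c("GENE", colnames(x)), collapse = "\t")
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format_sig(x[i, ], digits)), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

parse_gmt_token <- function(token, module, lineno) {
  m <- regmatches(token, regexec("^(.+)\\[([^][]*)\\]$", token))[[1L]]
  if (length(m) == 0L) {
    return(list(gene = token, weight = 1.0, sign_defined = FALSE))
  }
  w <- suppressWarnings(as.numeric(m[3L]))
  if (is.na(w) || !is.finite(w)) {
    stop("GMT line ", lineno, " (", module, "): cannot parse weight in token '", token, "'")
  }
  if (w == 0) {
    stop("GMT line ", lineno, " (", module, "): zero weight in token '", token, "'")
  }
  list(gene = m[2L], weight = w, sign_defined = TRUE)
}

#' Read module definitions from a GMT file
#'
#' One module per line: name, description, then gene tokens, tab-separated.
#' A plain token `GENE` yields weight +1 with no defined sign; the extended
#' token `GENE[w]` (`w` a signed non-zero real, e.g. `RB1[-1]`) yields a
#' signed weight used both for weighting the PC1 fit (by `|w|`) and for
#' orienting the component. Duplicate genes within a line keep the first
#' occurrence with a warning.
#'
#' @param path Path to the GMT file.
#' @return A named list of `roma_module` objects; each has `$name`,
#'   `$description` and `$genes`, a data frame with columns `gene`,
#'   `weight` and `sign_defined`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines)
  modules <- vector("list", sum(keep))
  j <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, ": fewer than 3 tab-separated fields")
    }
    tokens <- fields[-(1:2)]
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) == 0L) {
      stop("GMT line ", i, " (", fields[1L], "): module has no genes")
    }
    parsed <- lapply(tokens, parse_gmt_token, module = fields[1L], lineno = i)
    genes <- data.frame(
      gene = vapply(parsed, `[[`, character(1L), "gene"),
      weight = vapply(parsed, `[[`, numeric(1L), "weight"),
      sign_defined = vapply(parsed, `[[`, logical(1L), "sign_defined"),
      stringsAsFactors = FALSE
    )
    if (anyDuplicated(genes$gene)) {
      dups <- unique(genes$gene[duplicated(genes$gene)])
      warning("GMT line ", i, " (", fields[1L], "): duplicate gene token(s) ",
              paste(dups, collapse = ", "), "; keeping first occurrence")
      genes <- genes[!duplicated(genes$gene), , drop = FALSE]
      rownames(genes) <- NULL
    }
    j <- j + 1L
    modules[[j]] <- structure(
      list(name = fields[1L], description = fields[2L], genes = genes),
      class = "roma_module"
    )
  }
  modules <- modules[seq_len(j)]
  names(modules) <- vapply(modules, `[[`, character(1L), "name")
  modules
}

#' Write module definitions to a GMT file
#'
#' Inverse of [read_gmt()]; genes with a defined sign are rendered as
#' `GENE[w]`, unsigned genes as bare tokens.
#'
#' @param modules List of `roma_module` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(modules, path) {
  lines <- vapply(modules, function(m) {
    tok <- ifelse(m$genes$sign_defined,
                  paste0(m$genes$gene, "[", format_sig(m$genes$weight), "]"),
                  m$genes$gene)
    paste(c(m$name, m$description, tok), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Tab-delimited: first row feature names, first column sample names matching
#' the expression header.
#'
#' @param path Path to the annotation file.
#' @return A data frame with sample names as row names.
#' @export
read_sample_annotation <- function(path) {
  ann <- read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(ann[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample name in annotation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ann <- ann[, -1L, drop = FALSE]
  rownames(ann) <- ids
  ann
}

sanitize_filename <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' Write the three output tables of a ROMA run
#'
#' Produces, under `out_dir`: `module_scores.tsv` (one row per scored module:
#' sizes, L1, p(L1), L1/L2, p(L1/L2), outlier count, plus any extra columns
#' present in `scores` such as Benjamini-Hochberg adjusted p-values);
#' `module_activities.tsv` (modules x samples); and one
#' `projections/<module>.tsv` per module with per-gene PC1 loading, PC2
#' projection and outlier flag. Floats carry at least 6 significant digits.
#'
#' @param scores Data frame of module scores (see [run_roma()]).
#' @param activities Numeric matrix, rows = modules, columns = samples.
#' @param projections Named list of per-module data frames with columns
#'   `gene`, `weight`, `alpha_pc1`, `proj_pc2`, `is_outlier`.
#' @param out_dir Output directory, created if needed.
#' @param digits Significant digits for floats (>= 6).
#' @return Character vector of the files written, invisibly.
#' @export
write_roma_outputs <- function(scores, activities, projections, out_dir, digits = 7L) {
  stopifnot(digits >= 6L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  score_cols <- c("module", "size_in_file", "size_effective", "L1", "p_L1",
                  "L1_div_L2", "p_L1_div_L2", "n_outliers")
  if (nrow(scores) == 0L) {
    warning("no module scores to write; emitting header-only files")
    scores <- scores[, intersect(c(score_cols, names(scores)), names(scores)), drop = FALSE]
  }
  missing_cols <- setdiff(score_cols, names(scores))
  if (length(missing_cols)) {
    stop("score table lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(activities) != nrow(scores) ||
      (nrow(scores) > 0L &&
       !identical(rownames(activities), as.character(scores$module)))) {
    stop("activity matrix rows must match the score table's modules")
  }

  out_scores <- file.path(out_dir, "module_scores.tsv")
  sc <- scores
  for (cl in names(sc)) if (is.double(sc[[cl]])) sc[[cl]] <- format_sig(sc[[cl]], digits)
  write.table(sc, out_scores, sep = "\t", quote = FALSE, row.names = FALSE)

  out_act <- file.path(out_dir, "module_activities.tsv")
  header <- paste(c("MODULE", colnames(activities)), collapse = "\t")
  rows <- vapply(seq_len(nrow(activities)), function(i) {
    paste(c(rownames(activities)[i], format_sig(activities[i, ], digits)), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), out_act)

  proj_dir <- file.path(out_dir, "projections")
  dir.create(proj_dir, showWarnings = FALSE)
  proj_files <- character(0)
  for (nm in names(projections)) {
    p <- projections[[nm]]
    for (cl in names(p)) if (is.double(p[[cl]])) p[[cl]] <- format_sig(p[[cl]], digits)
    f <- file.path(proj_dir, paste0(sanitize_filename(nm), ".tsv"))
    write.table(p, f, sep = "\t", quote = FALSE, row.names = FALSE)
    proj_files <- c(proj_files, f)
  }
  invisible(c(out_scores, out_act, proj_files))
}

#' Read a module activity matrix written by [write_roma_outputs()]
#'
#' @param path Path to `module_activities.tsv`.
#' @return Numeric matrix, rows = modules, columns = samples.
#' @export
read_activities <- function(path) {
  read_expression(path)
}
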