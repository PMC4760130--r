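# Internal helpers shared across modules.

# Derive a per-stream seed from a master seed and a stream index so that
# adding streams (e.g. null-grid sizes) never perturbs existing ones.
# Kept strictly below 2^31 - 1.
derive_seed <- function(master, stream) {
  (as.double(master) * 48271 + as.double(stream) * 16807) %% 2147483587
}

roma_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[roma] ", ...)
}

# Tab-split that preserves trailing empty fields (strsplit drops them),
# so an empty missing-value cell at end of line still counts as a field.
split_tsv <- function(lines) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_expected <- nchar(lines) - nchar(gsub("\t", "", lines, fixed = TRUE)) + 1L
  Map(function(f, n) c(f, character(n - length(f))), fields, n_expected)
}

# Format a numeric table with at least `digits` significant digits.
format_sig <- function(x, digits = 7L) {
  ifelse(is.na(x), "NA", trimws(formatC(x, digits = digits, format = "g")))
}
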