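# Internal helpers shared across modules.

# Similarity weights are -log10(E), with E floored to avoid infinities.
EVALUE_FLOOR <- 1e-180
WEIGHT_CAP <- 180

evalue_to_weight <- function(evalue) {
  -log10(pmax(evalue, EVALUE_FLOOR))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same objects,
#' used throughout the test-suite to compare inferred orthogroups or
#' expression clusters with planted ground truth.
#'
#' @param x,y label vectors of equal length (any atomic type; compared as
#'   factors). Names are ignored; positions must correspond.
#' @return a single number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0L) return(NA_real_)
  tab <- table(as.character(x), as.character(y))
  n <- sum(tab)
  if (n < 2) return(1)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- comb2(as.vector(tab))
  sum_i <- comb2(rowSums(tab))
  sum_j <- comb2(colSums(tab))
  total <- n * (n - 1) / 2
  expected <- sum_i * sum_j / total
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Deterministic lexicographic sort independent of the user's locale.
lex_sort <- function(x) {
  x[order(x, method = "radix")]
}

lex_min <- function(x) lex_sort(x)[1L]

# Write a TSV with a provenance header (# key: value lines), used by the
# pipeline stage outputs.
write_tsv_prov <- function(df, path, prov = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(prov)) {
    for (k in names(prov)) {
      writeLines(sprintf("# %s: %s", k, prov[[k]]), con)
    }
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  read.delim(path, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
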