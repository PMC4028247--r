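#' Read a protein FASTA file into a sequence table
#'
#' Each record becomes one row; the identifier is the first
#' whitespace-delimited token of the header line and wrapped sequence lines
#' are concatenated. Sequences may contain \code{*} (stop codons from
#' in-silico translation); these are handled downstream by
#' \code{\link{qc_filter}}.
#'
#' @param path path to a FASTA file.
#' @param species species label attached to every record.
#' @return data.frame with columns \code{id}, \code{species},
#'   \code{residues}.
#' @export
read_fasta <- function(path, species) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    return(data.frame(id = character(), species = character(),
                      residues = character(), stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  res <- as.character(set)
  if (any(nchar(res) == 0L)) {
    stop("empty sequence block in ", path, " for id: ",
         paste(ids[nchar(res) == 0L], collapse = ", "))
  }
  data.frame(id = ids, species = species, residues = unname(res),
             stringsAsFactors = FALSE)
}

#' Write a sequence table to FASTA
#'
#' @param records data.frame as returned by \code{\link{read_fasta}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(records$residues)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Sequence quality filter
#'
#' Drops sequences that are shorter than \code{min_length} residues or whose
#' fraction of stop codons (\code{*}, counted over all residues including
#' the stops themselves) strictly exceeds \code{max_stop_fraction}. The
#' boundary is strict: a sequence with exactly the threshold fraction is
#' kept. Filtering is applied before any similarity search.
#'
#' @param records sequence data.frame (\code{id}, \code{species},
#'   \code{residues}).
#' @param min_length minimum residue count (default 10).
#' @param max_stop_fraction maximum tolerated stop fraction (default 0.20).
#' @return list with elements \code{kept} (data.frame) and \code{dropped}
#'   (data.frame with an extra \code{reason} column, \code{"short"} or
#'   \code{"stops"}; length takes precedence when both apply).
#' @export
qc_filter <- function(records, min_length = 10L, max_stop_fraction = 0.20) {
  stopifnot(min_length >= 1L,
            max_stop_fraction >= 0, max_stop_fraction <= 1)
  if (nrow(records) == 0L) {
    dropped <- records
    dropped$reason <- character(0)
    return(list(kept = records, dropped = dropped))
  }
  len <- nchar(records$residues)
  nstop <- nchar(records$residues) -
    nchar(gsub("*", "", records$residues, fixed = TRUE))
  frac <- nstop / len
  short <- len < min_length
  stops <- frac > max_stop_fraction
  reason <- ifelse(short, "short", ifelse(stops, "stops", NA_character_))
  drop <- short | stops
  dropped <- records[drop, , drop = FALSE]
  dropped$reason <- reason[drop]
  rownames(dropped) <- NULL
  kept <- records[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, dropped = dropped)
}

SIMILARITY_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                     "gapopen", "qstart", "qend", "sstart", "send",
                     "evalue", "bitscore")

#' Read BLAST-style 12-column tabular similarity hits
#'
#' Parses the conventional tab-separated format (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#' Lines with the wrong column count or a non-numeric e-value are rejected
#' with their line number.
#'
#' @param path path to the TSV file.
#' @return data.frame with the twelve standard columns; numeric columns
#'   converted.
#' @export
read_similarity_tabular <- function(path) {
  if (!file.exists(path)) stop("similarity file not found: ", path)
  lines <- readLines(path)
  lines_keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(lines_keep)
  if (length(idx) == 0L) return(empty_similarity_frame())
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- lengths(parts) != 12L
  if (any(bad)) {
    stop("malformed similarity line ", idx[which(bad)[1L]],
         ": expected 12 tab-separated columns, got ",
         lengths(parts)[which(bad)[1L]])
  }
  m <- do.call(rbind, parts)
  df <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                   stringsAsFactors = FALSE)
  numcols <- SIMILARITY_COLS[3:12]
  for (k in seq_along(numcols)) {
    v <- suppressWarnings(as.numeric(m[, k + 2L]))
    if (anyNA(v)) {
      stop("malformed similarity line ", idx[which(is.na(v))[1L]],
           ": non-numeric value in column ", numcols[k])
    }
    df[[numcols[k]]] <- v
  }
  if (any(df$evalue < 0)) {
    stop("negative e-value at line ", idx[which(df$evalue < 0)[1L]])
  }
  df
}

#' Write similarity hits in 12-column tabular format
#'
#' @param hits data.frame with the columns produced by
#'   \code{\link{read_similarity_tabular}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_similarity_tabular <- function(hits, path) {
  write.table(hits[, SIMILARITY_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Toy local pairwise similarity
#'
#' A deterministic Smith-Waterman local alignment (match +2, mismatch -1,
#' linear gap -2) standing in for an external all-vs-all search in tests and
#' simulations. The bitscore is the raw alignment score and the
#' pseudo-e-value is \eqn{E = n_a n_b 2^{-score}}, floored at 1e-180.
#'
#' @param a,b single-row sequence records (or lists with \code{id},
#'   \code{residues}).
#' @return one-row data.frame in the 12-column tabular layout (alignment
#'   coordinates are reported as 0; only score and e-value are used
#'   downstream).
#' @export
toy_local_similarity <- function(a, b) {
  if (nchar(a$residues) == 0L || nchar(b$residues) == 0L) {
    stop("toy_local_similarity: empty sequence")
  }
  score <- sw_score_cpp(a$residues, b$residues)
  ev <- toy_evalue(nchar(a$residues), nchar(b$residues), score)
  data.frame(qseqid = a$id, sseqid = b$id, pident = 0,
             length = 0, mismatch = 0, gapopen = 0,
             qstart = 0, qend = 0, sstart = 0, send = 0,
             evalue = ev, bitscore = as.numeric(score),
             stringsAsFactors = FALSE)
}

toy_evalue <- function(na, nb, score) {
  # 2^(-score) underflows for score > ~1075; work on log2 scale.
  lg2 <- log2(as.numeric(na)) + log2(as.numeric(nb)) - score
  ev <- 2^lg2
  max(ev, EVALUE_FLOOR)
}

#' All-vs-all toy similarity search
#'
#' Runs the toy aligner over every unordered pair of sequences (self-hits
#' excluded) and keeps hits with pseudo-e-value at or below \code{cutoff}.
#' Both directions of a pair are emitted, mirroring external search output.
#'
#' @param records sequence data.frame covering all species.
#' @param cutoff e-value cutoff (default 1e-5).
#' @return similarity hits data.frame in 12-column layout.
#' @export
toy_all_vs_all <- function(records, cutoff = 1e-5) {
  n <- nrow(records)
  if (n < 2L) return(empty_similarity_frame())
  scores <- sw_score_matrix_cpp(records$residues)
  len <- nchar(records$residues)
  out <- vector("list", n * (n - 1L))
  cnt <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ev <- toy_evalue(len[i], len[j], scores[i, j])
      if (ev <= cutoff) {
        cnt <- cnt + 1L
        out[[cnt]] <- c(i, j, ev, scores[i, j])
      }
    }
  }
  if (cnt == 0L) return(empty_similarity_frame())
  m <- do.call(rbind, out[seq_len(cnt)])
  i <- m[, 1]; j <- m[, 2]
  one <- data.frame(qseqid = records$id[i], sseqid = records$id[j],
                    pident = 0, length = 0,
                    mismatch = 0, gapopen = 0,
                    qstart = 0, qend = 0, sstart = 0, send = 0,
                    evalue = m[, 3], bitscore = m[, 4],
                    stringsAsFactors = FALSE)
  two <- one
  two$qseqid <- one$sseqid
  two$sseqid <- one$qseqid
  res <- rbind(one, two)
  rownames(res) <- NULL
  res
}

empty_similarity_frame <- function() {
  data.frame(qseqid = character(), sseqid = character(),
             pident = numeric(), length = numeric(),
             mismatch = numeric(), gapopen = numeric(),
             qstart = numeric(), qend = numeric(),
             sstart = numeric(), send = numeric(),
             evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}
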