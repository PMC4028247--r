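# Shared builders and independent oracles for the test-suite. Oracles are
# deliberately written as naive, loop-heavy reimplementations that share no
# code with the package internals.

rec <- function(id, residues, species = "sp1") {
  data.frame(id = id, species = species, residues = residues,
             stringsAsFactors = FALSE)
}

# Build similarity hits (one direction) from an edge table with explicit
# -log10 weights, so that build_graph(cutoff = 1) reproduces the weights
# exactly.
hits_from_weights <- function(edges) {
  data.frame(qseqid = edges$a, sseqid = edges$b, pident = 100,
             length = 10, mismatch = 0, gapopen = 0,
             qstart = 1, qend = 10, sstart = 1, send = 10,
             evalue = 10^(-edges$w), bitscore = edges$w,
             stringsAsFactors = FALSE)
}

graph_from_weights <- function(edges, proteins) {
  build_graph(hits_from_weights(edges), proteins, cutoff = 1)
}

# ---- independent Smith-Waterman oracle (naive full DP table) ----------
sw_oracle <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  H <- matrix(0, length(A) + 1, length(B) + 1)
  best <- 0
  for (i in seq_along(A)) {
    for (j in seq_along(B)) {
      s <- if (A[i] == B[j]) match else mismatch
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + s,
                             H[i, j + 1] + gap,
                             H[i + 1, j] + gap)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# ---- independent MCL oracle (explicit loops, no shared code) ----------
mcl_oracle <- function(W, inflation = 1.5, prune = 1e-5, tol = 1e-6,
                       iter_max = 100) {
  n <- nrow(W)
  A <- W
  for (i in seq_len(n)) {
    mx <- max(A[i, ])
    A[i, i] <- if (mx > 0) mx else 1
  }
  M <- matrix(0, n, n)
  for (j in seq_len(n)) M[, j] <- A[, j] / sum(A[, j])
  for (it in seq_len(iter_max)) {
    E <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        acc <- 0
        for (k in seq_len(n)) acc <- acc + M[i, k] * M[k, j]
        E[i, j] <- acc
      }
    }
    E <- E^inflation
    E[E < prune] <- 0
    for (j in seq_len(n)) {
      s <- sum(E[, j])
      if (s == 0) {
        E[j, j] <- 1
        s <- 1
      }
      E[, j] <- E[, j] / s
    }
    if (max(abs(E - M)) < tol) {
      M <- E
      break
    }
    M <- E
  }
  S <- (M > 0) | t(M > 0)
  comp <- rep(NA_integer_, n)
  cur <- 0
  for (s0 in seq_len(n)) {
    if (!is.na(comp[s0])) next
    cur <- cur + 1
    stack <- s0
    while (length(stack)) {
      v <- stack[1]
      stack <- stack[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      stack <- c(stack, which(S[v, ] & is.na(comp)))
    }
  }
  comp
}

# random small weighted graph for oracle comparisons
random_small_graph <- function(n, p_edge = 0.4) {
  ids <- sprintf("p%02d", seq_len(n))
  proteins <- data.frame(id = ids,
                         species = rep(c("s1", "s2"), length.out = n),
                         stringsAsFactors = FALSE)
  ed <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p_edge) {
        ed[[length(ed) + 1]] <- data.frame(
          a = ids[i], b = ids[j], w = round(runif(1, 1, 20), 2),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(ed) == 0) {
    ed[[1]] <- data.frame(a = ids[1], b = ids[2], w = 5,
                          stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, ed)
  list(graph = graph_from_weights(edges, proteins),
       proteins = proteins, edges = edges)
}

adjacency_from_edges <- function(edges, ids) {
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(edges))) {
    W[edges$a[r], edges$b[r]] <- edges$w[r]
    W[edges$b[r], edges$a[r]] <- edges$w[r]
  }
  W
}

# evidence-table row builder (zero-length compartments -> empty table)
ev_rows <- function(protein_id, compartments, source_kind, source_names) {
  if (length(compartments) == 0L) {
    return(data.frame(protein_id = character(), compartment = character(),
                      source_kind = character(), source_name = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(protein_id = protein_id, compartment = compartments,
             source_kind = source_kind, source_name = source_names,
             stringsAsFactors = FALSE)
}
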