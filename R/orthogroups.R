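#' Build a species-aware similarity graph from tabular hits
#'
#' Hits above the e-value cutoff are discarded, self-hits are dropped, and
#' the two directions of each pair (plus any duplicate hits) are averaged
#' into a single undirected edge with weight \eqn{w = -log10(max(E,
#' 1e-180))}. Edges are tagged inter- or intra-species; the species pair is
#' recorded for stratified normalization.
#'
#' @param hits similarity data.frame (12-column layout).
#' @param proteins data.frame with columns \code{id}, \code{species}
#'   covering the whole protein universe.
#' @param cutoff e-value cutoff; hits with \code{evalue > cutoff} are
#'   excluded (default 1e-5).
#' @return an object of class \code{similarity_graph}: list with
#'   \code{nodes} (id, species) and \code{edges} (a, b, w, category,
#'   species_pair).
#' @export
build_graph <- function(hits, proteins, cutoff = 1e-5) {
  stopifnot(!anyDuplicated(proteins$id))
  unknown <- setdiff(unique(c(hits$qseqid, hits$sseqid)), proteins$id)
  if (length(unknown) > 0L) {
    stop("similarity hit references unknown protein(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  hits <- hits[hits$evalue <= cutoff & hits$qseqid != hits$sseqid, ,
               drop = FALSE]
  if (nrow(hits) == 0L) {
    edges <- data.frame(a = character(), b = character(), w = numeric(),
                        category = character(), species_pair = character(),
                        stringsAsFactors = FALSE)
    return(structure(list(nodes = proteins, edges = edges),
                     class = "similarity_graph"))
  }
  w <- evalue_to_weight(hits$evalue)
  a <- pmin(hits$qseqid, hits$sseqid)
  b <- pmax(hits$qseqid, hits$sseqid)
  key <- paste(a, b, sep = "\r")
  agg <- tapply(w, key, mean)
  keys <- strsplit(names(agg), "\r", fixed = TRUE)
  a <- vapply(keys, `[`, "", 1L)
  b <- vapply(keys, `[`, "", 2L)
  sp <- setNames(proteins$species, proteins$id)
  sa <- sp[a]
  sb <- sp[b]
  edges <- data.frame(
    a = a, b = b, w = as.numeric(agg),
    category = ifelse(sa == sb, "intra", "inter"),
    species_pair = paste(pmin(sa, sb), pmax(sa, sb), sep = "|"),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$a, edges$b, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = proteins, edges = edges),
            class = "similarity_graph")
}

#' Normalize edge weights within species-pair strata
#'
#' Each edge weight is divided by the mean weight of all edges in its
#' (species pair, inter/intra) stratum, removing systematic between-species
#' scale differences before Markov clustering. A stratum with a single edge
#' normalizes to 1.
#'
#' @param g a \code{similarity_graph}.
#' @return the graph with normalized weights.
#' @export
normalize_weights <- function(g) {
  if (nrow(g$edges) == 0L) return(g)
  stratum <- paste(g$edges$species_pair, g$edges$category)
  mean_w <- tapply(g$edges$w, stratum, mean)
  g$edges$w <- g$edges$w / as.numeric(mean_w[stratum])
  g
}

graph_adjacency <- function(g) {
  ids <- g$nodes$id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(g$edges) > 0L) {
    ia <- match(g$edges$a, ids)
    ib <- match(g$edges$b, ids)
    A[cbind(ia, ib)] <- g$edges$w
    A[cbind(ib, ia)] <- g$edges$w
  }
  A
}

# Connected components of a symmetric adjacency/support matrix; returns an
# integer membership vector named by node id.
components_of <- function(S) {
  n <- nrow(S)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(S[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  setNames(comp, rownames(S))
}

#' Markov clustering of the similarity graph
#'
#' Classic MCL flow simulation: the column-stochastic transition matrix
#' (with self-loops weighted by each node's maximum incident weight) is
#' alternately squared (expansion) and raised elementwise to the inflation
#' power, pruned and re-normalized, until the matrix stabilizes. Clusters
#' are the connected components of the non-zero support of the attractor
#' matrix. Fully deterministic for a fixed node ordering.
#'
#' @param g a (normalized) \code{similarity_graph}.
#' @param inflation inflation exponent, > 1 (default 1.5).
#' @param prune_threshold entries below this are zeroed each iteration
#'   (default 1e-5).
#' @param tolerance convergence threshold on the max entry change
#'   (default 1e-6).
#' @param max_iterations iteration cap; if reached the current clustering is
#'   returned with attribute \code{converged = FALSE} and a warning.
#' @return data.frame (\code{group_id}, \code{protein_id}, \code{species},
#'   \code{source = "mcl"}); attribute \code{converged} logical.
#' @export
mcl <- function(g, inflation = 1.5, prune_threshold = 1e-5,
                tolerance = 1e-6, max_iterations = 100L) {
  stopifnot(inflation > 1, prune_threshold > 0)
  ids <- g$nodes$id
  A <- graph_adjacency(g)
  loop <- apply(A, 1L, max)
  loop[loop <= 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune_threshold] <- 0
    cs <- colSums(M2)
    zero <- cs == 0
    if (any(zero)) {
      # a fully pruned column keeps its self-loop
      M2[cbind(which(zero), which(zero))] <- 1
      cs[zero] <- 1
    }
    M2 <- sweep(M2, 2L, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", max_iterations, " iterations")
  }
  support <- (M > 0) | t(M > 0)
  comp <- components_of(support)
  groups_from_membership(comp, g$nodes, "mcl", converged = converged)
}

# Canonical group table from an integer membership vector named by protein
# id: groups ordered by their lexicographically smallest member.
groups_from_membership <- function(comp, nodes, source, converged = NULL) {
  sp <- setNames(nodes$species, nodes$id)
  split_ids <- split(names(comp), comp)
  split_ids <- lapply(split_ids, lex_sort)
  ord <- order(vapply(split_ids, `[`, "", 1L), method = "radix")
  split_ids <- split_ids[ord]
  gid <- sprintf("%s_%04d", source, seq_along(split_ids))
  out <- data.frame(
    group_id = rep(gid, lengths(split_ids)),
    protein_id = unlist(split_ids, use.names = FALSE),
    species = unname(sp[unlist(split_ids, use.names = FALSE)]),
    source = source,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(converged)) attr(out, "converged") <- converged
  out
}

#' Reciprocal best hits between two species
#'
#' A cross-species pair (a, b) is a seed pair when b is a's highest-weight
#' partner in species B and vice versa. Weight ties are broken by
#' lexicographic protein id, keeping the search deterministic.
#'
#' @param g a \code{similarity_graph}.
#' @param species_a,species_b the two species labels.
#' @return data.frame (\code{a}, \code{b}, \code{seed_weight}); zero rows
#'   when no cross edges exist.
#' @export
reciprocal_best_hits <- function(g, species_a, species_b) {
  stopifnot(species_a != species_b)
  sp <- setNames(g$nodes$species, g$nodes$id)
  e <- g$edges
  keep <- (sp[e$a] == species_a & sp[e$b] == species_b) |
          (sp[e$a] == species_b & sp[e$b] == species_a)
  e <- e[keep, , drop = FALSE]
  empty <- data.frame(a = character(), b = character(),
                      seed_weight = numeric(), stringsAsFactors = FALSE)
  if (nrow(e) == 0L) return(empty)
  # orient: column "pa" in species_a, "pb" in species_b
  swap <- sp[e$a] != species_a
  pa <- ifelse(swap, e$b, e$a)
  pb <- ifelse(swap, e$a, e$b)
  dirdf <- data.frame(pa = pa, pb = pb, w = e$w, stringsAsFactors = FALSE)
  best_partner <- function(from, to, w) {
    res <- new.env(parent = emptyenv())
    for (i in seq_along(from)) {
      prev <- res[[from[i]]]
      if (is.null(prev) || w[i] > prev$w ||
          (w[i] == prev$w && to[i] < prev$to)) {
        assign(from[i], list(to = to[i], w = w[i]), envir = res)
      }
    }
    res
  }
  best_b <- best_partner(dirdf$pa, dirdf$pb, dirdf$w)
  best_a <- best_partner(dirdf$pb, dirdf$pa, dirdf$w)
  seeds <- empty
  for (a_id in lex_sort(ls(best_b))) {
    cand <- best_b[[a_id]]
    back <- best_a[[cand$to]]
    if (!is.null(back) && back$to == a_id) {
      seeds <- rbind(seeds, data.frame(a = a_id, b = cand$to,
                                       seed_weight = cand$w,
                                       stringsAsFactors = FALSE))
    }
  }
  rownames(seeds) <- NULL
  seeds
}

#' Expand a seed pair with in-paralogs
#'
#' Adds same-species proteins whose intra-species similarity to the
#' corresponding seed orthologue is at least the seed weight (boundary
#' inclusive), the classic in-paralog criterion.
#'
#' @param seed one-row data.frame (\code{a}, \code{b}, \code{seed_weight}).
#' @param g a \code{similarity_graph}.
#' @return character vector of member protein ids (seed members first,
#'   then additions in lexicographic order).
#' @export
expand_in_paralogs <- function(seed, g) {
  sp <- setNames(g$nodes$species, g$nodes$id)
  e <- g$edges[g$edges$category == "intra", , drop = FALSE]
  grab <- function(anchor) {
    hit <- e[(e$a == anchor | e$b == anchor) & e$w >= seed$seed_weight, ,
             drop = FALSE]
    other <- ifelse(hit$a == anchor, hit$b, hit$a)
    lex_sort(unique(other))
  }
  unique(c(seed$a, seed$b, grab(seed$a), grab(seed$b)))
}

#' Merge pairwise orthologous groups across species pairs
#'
#' Transitive union: pairwise groups sharing at least one member are merged
#' (union-find), yielding disjoint multi-species groups.
#'
#' @param member_sets list of character vectors (members of each pairwise
#'   group).
#' @param nodes node table (\code{id}, \code{species}) of the graph.
#' @return data.frame (\code{group_id}, \code{protein_id}, \code{species},
#'   \code{source = "paranoid"}).
#' @export
merge_pairwise_groups <- function(member_sets, nodes) {
  all_ids <- lex_sort(unique(unlist(member_sets, use.names = FALSE)))
  parent <- setNames(seq_along(all_ids), all_ids)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  for (ms in member_sets) {
    idx <- match(ms, all_ids)
    for (k in idx[-1L]) {
      r1 <- find(idx[1L]); r2 <- find(k)
      if (r1 != r2) parent[[max(r1, r2)]] <- min(r1, r2)
    }
  }
  roots <- vapply(seq_along(all_ids), find, 1L)
  comp <- setNames(match(roots, unique(roots)), all_ids)
  sub_nodes <- nodes[nodes$id %in% all_ids, , drop = FALSE]
  groups_from_membership(comp, sub_nodes, "paranoid")
}

#' Full seed-and-expand orthology over all species pairs
#'
#' Convenience wrapper: reciprocal best hits for every unordered species
#' pair, in-paralog expansion of each seed, and transitive merging of the
#' pairwise groups. Proteins in no pairwise group are left out (singletons
#' are not fabricated).
#'
#' @param g a \code{similarity_graph}.
#' @return data.frame as from \code{\link{merge_pairwise_groups}}.
#' @export
paranoid_groups <- function(g) {
  species <- lex_sort(unique(g$nodes$species))
  member_sets <- list()
  for (i in seq_along(species)) {
    for (j in seq_along(species)) {
      if (j <= i) next
      seeds <- reciprocal_best_hits(g, species[i], species[j])
      for (r in seq_len(nrow(seeds))) {
        member_sets[[length(member_sets) + 1L]] <-
          expand_in_paralogs(seeds[r, , drop = FALSE], g)
      }
    }
  }
  merge_pairwise_groups(member_sets, g$nodes)
}

#' Combine both orthology inferences around the bait set
#'
#' For every bait protein the combined group is the union of everything
#' either algorithm co-grouped with it (union, not intersection, to cut
#' false negatives). Baits that end up in each other's groups are merged
#' into a single combined group. A non-bait protein claimed by two
#' different combined groups is assigned to the one whose bait it matches
#' with the higher direct similarity weight; an exact tie keeps it in both
#' with an ambiguity flag. Proteins co-grouped with no bait by either
#' algorithm stay unassigned.
#'
#' @param mcl_set,paranoid_set group tables from \code{\link{mcl}} and
#'   \code{\link{paranoid_groups}}.
#' @param core core-set data.frame with at least an \code{accession} column
#'   naming the bait proteins.
#' @param g the \code{similarity_graph} (for direct weights and the protein
#'   universe).
#' @return data.frame (\code{group_id}, \code{protein_id}, \code{species},
#'   \code{source = "combined"}, \code{ambiguous}).
#' @export
combine_orthogroups <- function(mcl_set, paranoid_set, core, g) {
  baits <- lex_sort(unique(core$accession))
  missing <- setdiff(baits, g$nodes$id)
  if (length(missing) > 0L) {
    stop("bait protein(s) absent from the protein universe: ",
         paste(missing, collapse = ", "))
  }
  co_members <- function(groups, bait) {
    gid <- groups$group_id[groups$protein_id == bait]
    if (length(gid) == 0L) return(bait)
    groups$protein_id[groups$group_id %in% gid]
  }
  per_bait <- lapply(baits, function(bt) {
    lex_sort(unique(c(co_members(mcl_set, bt), co_members(paranoid_set, bt))))
  })
  names(per_bait) <- baits

  # merge baits that claim one another
  parent <- setNames(seq_along(baits), baits)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  for (i in seq_along(baits)) {
    others <- intersect(per_bait[[i]], baits)
    for (ob in others) {
      r1 <- find(i); r2 <- find(match(ob, baits))
      if (r1 != r2) parent[[max(r1, r2)]] <- min(r1, r2)
    }
  }
  roots <- vapply(seq_along(baits), find, 1L)
  bait_groups <- split(baits, roots)
  bait_groups <- bait_groups[order(vapply(bait_groups, lex_min, ""))]

  A <- graph_adjacency(g)
  members <- lapply(bait_groups, function(bg) {
    lex_sort(unique(unlist(per_bait[bg], use.names = FALSE)))
  })

  # resolve non-bait proteins claimed by several combined groups
  tabulate_claims <- table(unlist(members, use.names = FALSE))
  contested <- setdiff(names(tabulate_claims[tabulate_claims > 1L]), baits)
  ambiguous <- character()
  for (p in contested) {
    holding <- which(vapply(members, function(m) p %in% m, TRUE))
    wts <- vapply(holding, function(k) {
      max(A[p, bait_groups[[k]]])
    }, 0)
    best <- max(wts)
    winners <- holding[wts == best]
    losers <- setdiff(holding, winners)
    for (k in losers) members[[k]] <- setdiff(members[[k]], p)
    if (length(winners) > 1L) ambiguous <- c(ambiguous, p)
  }

  sp <- setNames(g$nodes$species, g$nodes$id)
  gid <- sprintf("combined_%04d", seq_along(members))
  out <- data.frame(
    group_id = rep(gid, lengths(members)),
    protein_id = unlist(members, use.names = FALSE),
    species = unname(sp[unlist(members, use.names = FALSE)]),
    source = "combined",
    stringsAsFactors = FALSE)
  out$ambiguous <- out$protein_id %in% ambiguous
  rownames(out) <- NULL
  attr(out, "bait_groups") <- setNames(bait_groups, gid)
  out
}
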