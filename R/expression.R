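#' Read a gene x sample expression matrix
#'
#' Plain TSV with a header row of sample ids and gene ids in the first
#' column. Values are assumed already normalized (log scale); missing
#' values are rejected.
#'
#' @param path path to the TSV.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv_plain(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression matrix contains missing values")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  m
}

#' Read a sample-to-tissue map
#'
#' @param path TSV with columns \code{sample}, \code{tissue}.
#' @return data.frame (\code{sample}, \code{tissue}).
#' @export
read_tissue_map <- function(path) {
  df <- read_tsv_plain(path)
  stopifnot(all(c("sample", "tissue") %in% names(df)))
  df
}

#' Select representative samples per tissue
#'
#' Tissues with at most \code{max_n} samples keep all of them. Larger
#' tissues are reduced to the \code{max_n} samples closest (Euclidean
#' distance over genes) to the per-tissue median expression profile --
#' operationalizing "representative samples showing a median profile". An
#' average-linkage hierarchical clustering on correlation distance
#' (1 - Pearson) of the tissue's samples is computed and attached for audit,
#' but the selection criterion itself is nearest-to-median. Deterministic;
#' distance ties break by sample id.
#'
#' @param m expression matrix (genes x samples).
#' @param tissue_map data.frame (\code{sample}, \code{tissue}) covering
#'   every column of \code{m}.
#' @param max_n maximum samples kept per tissue (default 4).
#' @return data.frame (\code{sample}, \code{tissue}, \code{selected});
#'   attribute \code{dendrograms}: named list of \code{hclust} objects for
#'   tissues that were reduced.
#' @export
select_representatives <- function(m, tissue_map, max_n = 4L) {
  missing <- setdiff(colnames(m), tissue_map$sample)
  if (length(missing) > 0L) {
    stop("samples without tissue label: ", paste(missing, collapse = ", "))
  }
  tissue_map <- tissue_map[tissue_map$sample %in% colnames(m), ,
                           drop = FALSE]
  tissues <- lex_sort(unique(tissue_map$tissue))
  if (any(!tissues %in% tissue_map$tissue)) stop("tissue with 0 samples")
  sel <- rep(TRUE, nrow(tissue_map))
  dendros <- list()
  for (ts in tissues) {
    idx <- which(tissue_map$tissue == ts)
    samples <- tissue_map$sample[idx]
    if (length(samples) == 0L) stop("tissue with 0 samples: ", ts)
    if (length(samples) <= max_n) next
    sub <- m[, samples, drop = FALSE]
    cmat <- suppressWarnings(cor(sub))
    cmat[is.na(cmat)] <- 0
    dendros[[ts]] <- hclust(as.dist(1 - cmat), method = "average")
    med <- apply(sub, 1L, median)
    d <- sqrt(colSums((sub - med)^2))
    ord <- order(d, samples, method = "radix")
    keep <- samples[ord[seq_len(max_n)]]
    sel[idx] <- tissue_map$sample[idx] %in% keep
  }
  out <- data.frame(sample = tissue_map$sample, tissue = tissue_map$tissue,
                    selected = sel, stringsAsFactors = FALSE)
  attr(out, "dendrograms") <- dendros
  out
}

#' Per-tissue mean expression over selected samples
#'
#' @param m expression matrix (genes x samples).
#' @param selection data.frame from \code{\link{select_representatives}}
#'   (or any data.frame with \code{sample}, \code{tissue}, \code{selected}).
#' @return genes x tissues matrix of arithmetic means.
#' @export
tissue_means <- function(m, selection) {
  sel <- selection[selection$selected, , drop = FALSE]
  tissues <- lex_sort(unique(sel$tissue))
  out <- vapply(tissues, function(ts) {
    cols <- sel$sample[sel$tissue == ts]
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), tissues))
  out
}

#' Fit k-means on the gene x tissue matrix
#'
#' Euclidean k-means, best of \code{restarts} random initializations drawn
#' deterministically from \code{seed}. Inertia is the total within-cluster
#' sum of squared distances.
#'
#' @param gt gene x tissue matrix.
#' @param k number of clusters (1 <= k <= number of genes).
#' @param seed RNG seed.
#' @param restarts number of random restarts (default 10).
#' @param warm_centers optional matrix of starting centers for one extra
#'   (non-random) run; used by \code{\link{elbow_scan}} to make the curve
#'   non-increasing by construction.
#' @return list of class \code{cluster_model}: \code{k},
#'   \code{assignments} (named integer vector), \code{centroids},
#'   \code{inertia}, \code{seed}, \code{restarts}.
#' @export
kmeans_fit <- function(gt, k, seed = 1L, restarts = 10L,
                       warm_centers = NULL) {
  n <- nrow(gt)
  if (k > n) stop("k (", k, ") exceeds the number of genes (", n, ")")
  stopifnot(k >= 1L)
  best <- NULL
  run_one <- function(centers) {
    # kmeans() rejects duplicated starting centers; such a restart is
    # simply skipped
    tryCatch(
      suppressWarnings(kmeans(gt, centers = centers, iter.max = 100L,
                              algorithm = "Lloyd")),
      error = function(e) NULL)
  }
  uniq <- which(!duplicated(gt))
  set.seed(seed)
  for (r in seq_len(restarts)) {
    centers <- gt[kmeanspp_centers(gt, k), , drop = FALSE]
    fit <- run_one(centers)
    if (!is.null(fit) &&
        (is.null(best) || fit$tot.withinss < best$tot.withinss)) best <- fit
  }
  if (!is.null(warm_centers)) {
    fit <- run_one(warm_centers)
    if (!is.null(fit) &&
        (is.null(best) || fit$tot.withinss < best$tot.withinss)) best <- fit
  }
  if (is.null(best)) {
    # degenerate input: fewer distinct profiles than clusters; fit on the
    # distinct rows, which already reaches inertia 0
    kk <- min(k, length(uniq))
    best <- suppressWarnings(kmeans(gt, centers = gt[uniq[seq_len(kk)], ,
                                                     drop = FALSE],
                                    iter.max = 100L, algorithm = "Lloyd"))
  }
  structure(list(k = k,
                 assignments = setNames(best$cluster, rownames(gt)),
                 centroids = best$centers,
                 inertia = best$tot.withinss,
                 seed = seed, restarts = restarts),
            class = "cluster_model")
}

#' Scan cluster counts and record the elbow curve
#'
#' Fits k-means for each k in \code{k_range} and records the best-of-
#' restarts inertia ("distance to the optimal solution"; the optimal
#' solution, one gene per cluster, has inertia 0). On top of the random
#' restarts, each k is also warm-started from the previous best solution's
#' centroids plus the worst-fit gene, which guarantees a non-increasing
#' curve.
#'
#' @param gt gene x tissue matrix.
#' @param k_range integer vector of cluster counts (default 1:50, clipped
#'   to the gene count).
#' @param seed RNG seed.
#' @param restarts restarts per k (default 10).
#' @return data.frame (\code{k}, \code{inertia}); attribute
#'   \code{default_k = 10} records the working cluster count.
#' @export
elbow_scan <- function(gt, k_range = 1:50, seed = 1L, restarts = 10L) {
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 1L & k_range <= nrow(gt)]
  prev <- NULL
  rows <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    warm <- NULL
    if (!is.null(prev) && prev$k == k - 1L) {
      # previous centroids plus the gene farthest from its centroid
      resid <- rowSums((gt - prev$centroids[prev$assignments, ,
                                            drop = FALSE])^2)
      worst <- which.max(resid)
      warm <- rbind(prev$centroids, gt[worst, , drop = FALSE])
      rownames(warm) <- NULL
    }
    fit <- kmeans_fit(gt, k, seed = seed + k, restarts = restarts,
                      warm_centers = warm)
    if (!is.null(prev) && fit$inertia > prev$inertia) fit <- prev_as_k(prev)
    rows[[i]] <- data.frame(k = k, inertia = fit$inertia)
    prev <- fit
  }
  out <- do.call(rbind, rows)
  attr(out, "default_k") <- 10L
  out
}

# should never trigger given the warm start, but keeps the monotonicity
# contract airtight against Lloyd's early-stop quirks
prev_as_k <- function(prev) prev

# k-means++ seeding: first center uniform, later centers sampled with
# probability proportional to the squared distance to the nearest chosen
# center. Greatly reduces the chance that a restart misses a well-separated
# cluster entirely.
kmeanspp_centers <- function(gt, k) {
  n <- nrow(gt)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  if (k == 1L) return(centers)
  d2 <- rowSums((gt - rep(gt[centers[1L], ], each = n))^2)
  for (i in 2:k) {
    if (sum(d2) <= 0) {
      # all remaining points coincide with a center; fall back to uniform
      centers[i] <- sample.int(n, 1L)
    } else {
      centers[i] <- sample.int(n, 1L, prob = d2)
    }
    nd <- rowSums((gt - rep(gt[centers[i], ], each = n))^2)
    d2 <- pmin(d2, nd)
  }
  centers
}

#' Per-cluster, per-tissue median expression
#'
#' @param model a \code{cluster_model}.
#' @param gt gene x tissue matrix used for the fit.
#' @return clusters x tissues matrix of medians; rows of empty clusters
#'   (possible when Lloyd drops a center) are \code{NA}.
#' @export
cluster_tissue_medians <- function(model, gt) {
  ks <- seq_len(model$k)
  out <- matrix(NA_real_, length(ks), ncol(gt),
                dimnames = list(paste0("cluster_", ks), colnames(gt)))
  for (k in ks) {
    genes <- names(model$assignments)[model$assignments == k]
    if (length(genes) == 0L) next
    out[k, ] <- apply(gt[genes, , drop = FALSE], 2L, median)
  }
  out
}

#' Localization distribution per expression cluster
#'
#' Counts cluster members per consensus compartment. Multi-compartment
#' calls contribute fractionally (1/number of tied compartments) so that
#' row sums equal cluster sizes; genes without a call are counted under
#' \code{"unknown"}.
#'
#' @param model a \code{cluster_model}.
#' @param calls consensus table (\code{protein_id}, \code{compartments}).
#' @return clusters x compartments numeric matrix.
#' @export
localization_distribution <- function(model, calls) {
  comp_of <- setNames(calls$compartments, calls$protein_id)
  genes <- names(model$assignments)
  comps <- comp_of[genes]
  comps[is.na(comps)] <- "unknown"
  split_comps <- strsplit(comps, "/", fixed = TRUE)
  all_comps <- lex_sort(unique(unlist(split_comps)))
  ks <- seq_len(model$k)
  out <- matrix(0, length(ks), length(all_comps),
                dimnames = list(paste0("cluster_", ks), all_comps))
  for (i in seq_along(genes)) {
    k <- model$assignments[[i]]
    cc <- split_comps[[i]]
    out[k, cc] <- out[k, cc] + 1 / length(cc)
  }
  out
}
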