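AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Default simulation configuration
#'
#' The stated world of the synthetic benchmark: four plant-like species and
#' one fungal outgroup, 30 ancestral families evolving down a star tree
#' with modest lineage-specific duplication, light per-site substitution,
#' occasional domain gain/loss, localization truth with configurable
#' predictor accuracies, and an expression matrix with 10 planted
#' tissue-specific clusters. See the methods vignette for the rationale
#' behind each default.
#'
#' @param seed mandatory RNG seed.
#' @param ... overrides for any field of the returned list.
#' @return named list of simulation parameters.
#' @export
sim_config <- function(seed, ...) {
  cfg <- list(
    seed = seed,
    n_species = 5L,
    species = NULL,                 # filled below
    n_families = 30L,
    duplication_prob = 0.2,
    substitution_prob = 0.05,
    sequence_length = 120L,
    domain_alphabet_size = 10L,
    domain_gain_prob = 0.1,
    domain_loss_prob = 0.1,
    n_short_decoys = 2L,
    n_stop_decoys = 2L,
    compartment_freqs = NULL,       # uniform over the 11 compartments
    predictor_accuracy = 0.7,
    n_predictors = 20L,
    expr_n_clusters = 10L,
    expr_genes_per_cluster = 50L,
    expr_tissues = paste0("tissue", 1:9),
    expr_samples_per_tissue = 6L,
    expr_profile_sd = 3,
    expr_noise_sd = 0.5)
  over <- list(...)
  cfg[names(over)] <- over
  if (is.null(cfg$species)) {
    cfg$species <- c(paste0("plant", seq_len(cfg$n_species - 1L)),
                     "outgroup")
  }
  stopifnot(cfg$duplication_prob >= 0, cfg$duplication_prob <= 1,
            cfg$substitution_prob >= 0, cfg$substitution_prob <= 1,
            cfg$domain_gain_prob >= 0, cfg$domain_gain_prob <= 1,
            cfg$domain_loss_prob >= 0, cfg$domain_loss_prob <= 1,
            cfg$n_families >= 1L, length(cfg$species) >= 2L)
  cfg
}

random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, p) {
  if (p <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < p
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(cc) {
      sample(setdiff(AA_ALPHABET, cc), 1L)
    }, "")
  }
  paste(chars, collapse = "")
}

evolve_domains <- function(arch, gain_p, loss_p, alphabet) {
  if (length(arch) > 1L && runif(1) < loss_p) {
    arch <- arch[-sample.int(length(arch), 1L)]
  }
  if (runif(1) < gain_p) {
    pos <- sample.int(length(arch) + 1L, 1L)
    arch <- append(arch, sample(alphabet, 1L), after = pos - 1L)
  }
  arch
}

#' Simulate multi-species proteomes with planted orthology
#'
#' Each ancestral family (a random protein with a random 1-3 domain
#' architecture) evolves independently down a star tree: per species the
#' sequence accumulates per-site substitutions, the architecture may gain or
#' lose a domain, and with \code{duplication_prob} a lineage-specific
#' duplicate (co-orthologue, carrying one extra round of substitution and
#' domain evolution) is created. Short and stop-codon-laden decoy sequences
#' are appended to exercise the quality filter; decoys carry no family
#' label. One member per family in the last species (the outgroup) is
#' flagged as a core-set bait.
#'
#' @param cfg configuration from \code{\link{sim_config}}.
#' @return list: \code{records} (sequence data.frame), \code{domains}
#'   (data.frame protein_id, accession, name, ali_start, ali_end, evalue),
#'   \code{truth} (data.frame protein_id, species, family, is_decoy),
#'   \code{core} (core-set data.frame of bait proteins), \code{config}.
#' @export
simulate_proteomes <- function(cfg) {
  set.seed(cfg$seed)
  alphabet <- sprintf("DOM%04d", seq_len(cfg$domain_alphabet_size))
  fams <- sprintf("fam%03d", seq_len(cfg$n_families))
  anc_seq <- setNames(
    vapply(fams, function(f) random_protein(cfg$sequence_length), ""),
    fams)
  anc_arch <- setNames(lapply(fams, function(f) {
    sample(alphabet, sample(1:3, 1L))
  }), fams)

  recs <- list()
  doms <- list()
  truth <- list()
  for (sp in cfg$species) {
    for (f in fams) {
      n_copies <- 1L + rbinom(1L, 1L, cfg$duplication_prob)
      seq0 <- mutate_protein(anc_seq[[f]], cfg$substitution_prob)
      arch0 <- evolve_domains(anc_arch[[f]], cfg$domain_gain_prob,
                              cfg$domain_loss_prob, alphabet)
      for (cp in seq_len(n_copies)) {
        pid <- sprintf("%s_%s_c%d", sp, f, cp)
        sq <- seq0
        ar <- arch0
        if (cp > 1L) {
          sq <- mutate_protein(sq, cfg$substitution_prob)
          ar <- evolve_domains(ar, cfg$domain_gain_prob,
                               cfg$domain_loss_prob, alphabet)
        }
        recs[[pid]] <- data.frame(id = pid, species = sp, residues = sq,
                                  stringsAsFactors = FALSE)
        truth[[pid]] <- data.frame(protein_id = pid, species = sp,
                                   family = f, is_decoy = FALSE,
                                   stringsAsFactors = FALSE)
        if (length(ar) > 0L) {
          start <- cumsum(c(1L, rep(12L, length(ar) - 1L)))
          doms[[pid]] <- data.frame(
            protein_id = pid, accession = ar, name = tolower(ar),
            ali_start = start, ali_end = start + 9L,
            evalue = 10^-runif(length(ar), 10, 50),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  # QC decoys, attached to the first species
  sp1 <- cfg$species[1L]
  for (i in seq_len(cfg$n_short_decoys)) {
    pid <- sprintf("%s_short_d%d", sp1, i)
    recs[[pid]] <- data.frame(id = pid, species = sp1,
                              residues = random_protein(5L),
                              stringsAsFactors = FALSE)
    truth[[pid]] <- data.frame(protein_id = pid, species = sp1,
                               family = NA_character_, is_decoy = TRUE,
                               stringsAsFactors = FALSE)
  }
  for (i in seq_len(cfg$n_stop_decoys)) {
    pid <- sprintf("%s_stops_d%d", sp1, i)
    body <- random_protein(30L)
    stops <- paste(rep("*", 15L), collapse = "")
    recs[[pid]] <- data.frame(id = pid, species = sp1,
                              residues = paste0(body, stops),
                              stringsAsFactors = FALSE)
    truth[[pid]] <- data.frame(protein_id = pid, species = sp1,
                               family = NA_character_, is_decoy = TRUE,
                               stringsAsFactors = FALSE)
  }

  records <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  domains <- do.call(rbind, c(doms, list(make.row.names = FALSE)))
  truth_df <- do.call(rbind, c(truth, list(make.row.names = FALSE)))

  outgroup <- cfg$species[length(cfg$species)]
  core <- data.frame(
    factor_id = fams,
    family = rep(c("COP-II", "COP-I", "CCV", "Retromer/ESCRT",
                   "RabGTPase", "Tethering", "SNARE"),
                 length.out = length(fams)),
    species = "yeast",
    accession = sprintf("%s_%s_c1", outgroup, fams),
    evidence = "experimental",
    stringsAsFactors = FALSE)

  list(records = records, domains = domains, truth = truth_df,
       core = core, config = cfg)
}

#' All-vs-all toy similarity for a simulated proteome
#'
#' Runs the toy Smith-Waterman search over the QC-passing sequences and
#' returns hits in the 12-column tabular layout.
#'
#' @param records sequence data.frame (post-QC).
#' @param cutoff e-value cutoff (default 1e-5).
#' @return similarity data.frame.
#' @export
simulate_similarity <- function(records, cutoff = 1e-5) {
  toy_all_vs_all(records, cutoff = cutoff)
}

#' Simulate localization truth and noisy predictor calls
#'
#' Each protein receives a true compartment drawn from
#' \code{compartment_freqs} (uniform by default). Every configured predictor
#' reports the true compartment with probability \code{accuracy} and
#' otherwise a uniformly chosen wrong compartment. Experimental records are
#' emitted for a configurable fraction of proteins.
#'
#' @param protein_ids character vector of proteins to annotate.
#' @param cfg configuration from \code{\link{sim_config}}.
#' @param accuracy per-predictor accuracy (default from \code{cfg}).
#' @param experimental_fraction fraction of proteins that also get a single
#'   experimental (MS) record of the true compartment (default 0).
#' @return list: \code{truth} (data.frame protein_id, compartment),
#'   \code{evidence} (long data.frame protein_id, compartment, source_kind,
#'   source_name).
#' @export
simulate_predictor_calls <- function(protein_ids, cfg,
                                     accuracy = cfg$predictor_accuracy,
                                     experimental_fraction = 0) {
  set.seed(cfg$seed + 1L)
  freqs <- cfg$compartment_freqs %||%
    setNames(rep(1 / length(COMPARTMENTS), length(COMPARTMENTS)),
             COMPARTMENTS)
  truth <- data.frame(
    protein_id = protein_ids,
    compartment = sample(names(freqs), length(protein_ids),
                         replace = TRUE, prob = freqs),
    stringsAsFactors = FALSE)
  tools <- sprintf("pred%02d", seq_len(cfg$n_predictors))
  ev <- list()
  for (tl in tools) {
    correct <- runif(length(protein_ids)) < accuracy
    wrong <- vapply(truth$compartment, function(tc) {
      sample(setdiff(COMPARTMENTS, tc), 1L)
    }, "")
    ev[[tl]] <- data.frame(
      protein_id = protein_ids,
      compartment = ifelse(correct, truth$compartment, wrong),
      source_kind = "predictor",
      source_name = tl,
      stringsAsFactors = FALSE)
  }
  if (experimental_fraction > 0) {
    take <- runif(length(protein_ids)) < experimental_fraction
    if (any(take)) {
      ev[["ms"]] <- data.frame(
        protein_id = protein_ids[take],
        compartment = truth$compartment[take],
        source_kind = "experimental_ms",
        source_name = "synthetic_ms",
        stringsAsFactors = FALSE)
    }
  }
  evidence <- do.call(rbind, c(ev, list(make.row.names = FALSE)))
  list(truth = truth, evidence = evidence)
}

#' Simulate an expression matrix with planted tissue clusters
#'
#' Each planted cluster has its own per-tissue mean profile (i.i.d. normal
#' with sd \code{expr_profile_sd}); gene values are the cluster profile plus
#' independent Gaussian noise, replicated over
#' \code{expr_samples_per_tissue} samples per tissue.
#'
#' @param cfg configuration from \code{\link{sim_config}}.
#' @return list: \code{matrix} (genes x samples), \code{tissue_map}
#'   (data.frame sample, tissue), \code{truth} (data.frame gene, cluster),
#'   \code{profiles} (clusters x tissues matrix).
#' @export
simulate_expression <- function(cfg) {
  set.seed(cfg$seed + 2L)
  k <- cfg$expr_n_clusters
  gpc <- cfg$expr_genes_per_cluster
  tissues <- cfg$expr_tissues
  spt <- cfg$expr_samples_per_tissue
  profiles <- matrix(rnorm(k * length(tissues), 0, cfg$expr_profile_sd),
                     k, length(tissues),
                     dimnames = list(paste0("cluster_", seq_len(k)),
                                     tissues))
  genes <- sprintf("gene%04d", seq_len(k * gpc))
  cluster_of <- rep(seq_len(k), each = gpc)
  samples <- as.vector(vapply(tissues, function(ts) {
    paste0(ts, "_s", seq_len(spt))
  }, character(spt)))
  tissue_map <- data.frame(
    sample = samples,
    tissue = rep(tissues, each = spt),
    stringsAsFactors = FALSE)
  m <- matrix(0, length(genes), length(samples),
              dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    ts_idx <- match(tissue_map$tissue[j], tissues)
    m[, j] <- profiles[cluster_of, ts_idx] +
      rnorm(length(genes), 0, cfg$expr_noise_sd)
  }
  list(matrix = m, tissue_map = tissue_map,
       truth = data.frame(gene = genes, cluster = cluster_of,
                          stringsAsFactors = FALSE),
       profiles = profiles)
}
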