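#' Assemble a pipeline configuration
#'
#' Paths may be \code{NULL} when the corresponding stage is driven by the
#' synthetic generator (\code{simulate = TRUE}).
#'
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed recorded in every output header.
#' @param fasta named character vector (species -> FASTA path), or
#'   \code{NULL}.
#' @param similarity path to a 12-column similarity TSV, or \code{NULL} to
#'   run the built-in toy all-vs-all search.
#' @param domains path to a domain-hit TSV.
#' @param core path to a core-set TSV (factor_id, family, species,
#'   accession, evidence).
#' @param evidence path to a localization evidence TSV.
#' @param expression path to an expression matrix TSV.
#' @param tissue_map path to a sample-tissue TSV.
#' @param simulate generate all inputs synthetically (default when no paths
#'   are given).
#' @param min_length,max_stop_fraction QC parameters.
#' @param evalue_cutoff,inflation Markov-clustering parameters.
#' @param tier localization tier, \code{"high"} or \code{"low"}.
#' @param k,k_range,max_samples_per_tissue,restarts expression parameters.
#' @param collapse_repeats collapse consecutive domain repeats before
#'   classification.
#' @param sim_overrides named list of overrides forwarded to
#'   \code{\link{sim_config}} when \code{simulate = TRUE} (e.g. smaller
#'   worlds for quick runs).
#' @return named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            fasta = NULL, similarity = NULL,
                            domains = NULL, core = NULL, evidence = NULL,
                            expression = NULL, tissue_map = NULL,
                            simulate = is.null(fasta),
                            min_length = 10L, max_stop_fraction = 0.20,
                            evalue_cutoff = 1e-5, inflation = 1.5,
                            tier = c("high", "low"),
                            k = 10L, k_range = 1:50,
                            max_samples_per_tissue = 4L, restarts = 10L,
                            collapse_repeats = FALSE,
                            sim_overrides = list()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), fasta = fasta,
                 similarity = similarity, domains = domains, core = core,
                 evidence = evidence, expression = expression,
                 tissue_map = tissue_map, simulate = simulate,
                 min_length = min_length,
                 max_stop_fraction = max_stop_fraction,
                 evalue_cutoff = evalue_cutoff, inflation = inflation,
                 tier = match.arg(tier), k = k, k_range = k_range,
                 max_samples_per_tissue = max_samples_per_tissue,
                 restarts = restarts, collapse_repeats = collapse_repeats,
                 sim_overrides = sim_overrides),
            class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dump_cfg <- cfg
  dump_cfg$out_dir <- NULL
  writeLines(paste(names(dump_cfg),
                   vapply(dump_cfg, function(x)
                     paste(format(x), collapse = ","), "")), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' QC, similarity (external or toy), both orthology algorithms, combination
#' around the bait set, bait selection and domain-architecture
#' classification, localization consensus and cross-species summary, and
#' tissue-expression clustering. Every output TSV carries a provenance
#' header (package version, seed, config hash) and the run writes a JSON
#' manifest listing all outputs. Fully deterministic under a fixed
#' configuration.
#'
#' @param cfg a \code{pipeline_config}.
#' @return the output directory, invisibly; stage results are also returned
#'   in the \code{"results"} attribute.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(package = "vesitra",
               version = as.character(utils::packageVersion("vesitra")),
               seed = cfg$seed, config = config_hash(cfg))
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    write_tsv_prov(df, path, prov)
    outputs[[length(outputs) + 1L]] <<- name
    path
  }
  stage <- function(name, expr) {
    message(sprintf("[vesitra] stage %-18s ...", name), appendLF = FALSE)
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf(" done (%.1fs)",
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  # ---- inputs -------------------------------------------------------
  sim <- NULL
  if (cfg$simulate) {
    sim <- stage("simulate", simulate_proteomes(
      do.call(sim_config, c(list(seed = cfg$seed), cfg$sim_overrides))))
    records <- sim$records
    core <- sim$core
    domains_df <- sim$domains
  } else {
    records <- stage("read-fasta", {
      do.call(rbind, lapply(names(cfg$fasta), function(sp) {
        read_fasta(cfg$fasta[[sp]], sp)
      }))
    })
    core <- read_tsv_plain(cfg$core)
    domains_df <- read_tsv_plain(cfg$domains)
  }

  # ---- qc -----------------------------------------------------------
  qc <- stage("qc", qc_filter(records, cfg$min_length,
                              cfg$max_stop_fraction))
  emit(qc$dropped[, c("id", "species", "reason")], "qc_dropped.tsv")

  # ---- similarity ---------------------------------------------------
  hits <- if (is.null(cfg$similarity)) {
    stage("similarity", toy_all_vs_all(qc$kept, cfg$evalue_cutoff))
  } else {
    stage("similarity", read_similarity_tabular(cfg$similarity))
  }
  emit(hits, "similarity.tsv")

  # ---- orthology ----------------------------------------------------
  proteins <- qc$kept[, c("id", "species")]
  g <- stage("graph", normalize_weights(
    build_graph(hits, proteins, cfg$evalue_cutoff)))
  mcl_set <- stage("mcl", mcl(g, inflation = cfg$inflation))
  par_set <- stage("paranoid", paranoid_groups(g))
  combined <- stage("combine",
                    combine_orthogroups(mcl_set, par_set, core, g))
  all_groups <- rbind(
    cbind(mcl_set, ambiguous = FALSE),
    cbind(par_set, ambiguous = FALSE),
    combined[, c("group_id", "protein_id", "species", "source",
                 "ambiguous")])
  emit(all_groups, "orthogroups.tsv")

  # ---- domains ------------------------------------------------------
  archs <- stage("domains", {
    tmp <- tempfile(fileext = ".tsv")
    write.table(domains_df, tmp, sep = "\t", quote = FALSE,
                row.names = FALSE)
    on.exit(unlink(tmp))
    read_domain_table(tmp)
  })
  cls <- stage("classify",
               classify_groups(combined, archs, core,
                               collapse_repeats = cfg$collapse_repeats))
  emit(cls$assignments, "class_assignments.tsv")
  summ <- summarize_classes(cls$assignments, core)
  emit(summ$table, "class_summary.tsv")

  counts <- stage("conservation", {
    bait_groups <- attr(combined, "bait_groups")
    factor_of <- setNames(core$factor_id, core$accession)
    rows <- list()
    for (gid in names(bait_groups)) {
      fids <- unique(unname(factor_of[bait_groups[[gid]]]))
      mem <- combined[combined$group_id == gid, , drop = FALSE]
      for (fid in fids) {
        tab <- table(mem$species)
        rows[[paste(gid, fid)]] <- data.frame(
          factor_id = fid, species = names(tab),
          n = as.integer(tab), stringsAsFactors = FALSE)
      }
    }
    agg <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    tapply_df <- aggregate(n ~ factor_id + species, data = agg, FUN = sum)
    tapply_df
  })
  cons <- conservation_summary(counts)
  emit(as.data.frame(cons$presence), "presence_absence.tsv")

  # ---- localization -------------------------------------------------
  loc <- stage("localize", {
    if (cfg$simulate) {
      simloc <- simulate_predictor_calls(
        proteins$id, sim$config,
        experimental_fraction = if (cfg$tier == "high") 0.3 else 0)
      evd <- simloc$evidence
      if (cfg$tier == "low") {
        evd <- low_tier_view(evd)
      }
      calls <- consensus_calls(evd, tier = cfg$tier,
                               proteins = proteins$id)
      attr(calls, "truth") <- simloc$truth
      calls
    } else {
      evd <- read_tsv_plain(cfg$evidence)
      consensus_calls(evd, tier = cfg$tier, proteins = proteins$id)
    }
  })
  emit(loc, "localization_consensus.tsv")

  plant_species <- setdiff(unique(proteins$species),
                           c("outgroup", "yeast"))
  xs <- stage("cross-species",
              cross_species_count(combined, attr(combined, "bait_groups"),
                                  loc, core, "plastid", plant_species))
  emit(xs, "cross_species_plastid.tsv")

  # ---- expression ---------------------------------------------------
  expr <- stage("expression", {
    if (cfg$simulate) {
      sime <- simulate_expression(sim$config)
      list(m = sime$matrix, map = sime$tissue_map, truth = sime$truth)
    } else {
      list(m = read_expression_matrix(cfg$expression),
           map = read_tissue_map(cfg$tissue_map), truth = NULL)
    }
  })
  selection <- select_representatives(expr$m, expr$map,
                                      cfg$max_samples_per_tissue)
  emit(selection, "sample_selection.tsv")
  gt <- tissue_means(expr$m, selection)
  emit(data.frame(gene = rownames(gt), gt, check.names = FALSE),
       "tissue_means.tsv")
  elbow <- stage("elbow", elbow_scan(gt, cfg$k_range, seed = cfg$seed,
                                     restarts = cfg$restarts))
  emit(elbow, "elbow.tsv")
  model <- stage("kmeans", kmeans_fit(gt, cfg$k, seed = cfg$seed,
                                      restarts = cfg$restarts))
  emit(data.frame(gene = names(model$assignments),
                  cluster = unname(model$assignments)),
       "cluster_assignments.tsv")
  med <- cluster_tissue_medians(model, gt)
  emit(data.frame(cluster = rownames(med), med, check.names = FALSE),
       "cluster_tissue_medians.tsv")

  manifest <- list(version = prov$version, seed = cfg$seed,
                   config = prov$config, outputs = outputs)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  results <- list(qc = qc, graph = g, mcl = mcl_set, paranoid = par_set,
                  combined = combined, classes = cls, summary = summ,
                  conservation = cons, localization = loc,
                  cross_species = xs, selection = selection,
                  tissue_means = gt, elbow = elbow, model = model,
                  medians = med, sim = sim)
  invisible(structure(cfg$out_dir, results = results))
}

# restrict a simulated 20-tool evidence table to the six-tool low tier and
# rename the tools to the roster names
low_tier_view <- function(evidence, roster = default_low_tier_roster()) {
  preds <- evidence[evidence$source_kind == "predictor", , drop = FALSE]
  tools <- lex_sort(unique(preds$source_name))[seq_len(nrow(roster))]
  sub <- preds[preds$source_name %in% tools, , drop = FALSE]
  sub$source_name <- roster$tool[match(sub$source_name, tools)]
  kind <- setNames(roster$kind, roster$tool)
  target <- setNames(roster$target, roster$tool)
  # specialist tools only speak up for their own compartment
  is_single <- kind[sub$source_name] == "single"
  off_target <- is_single & sub$compartment != target[sub$source_name]
  sub$compartment[off_target] <- "none"
  # three-class tools collapse everything outside {plastid, mitochondrion}
  # into the secretory/other bucket, which we encode as cytosol
  is_triple <- kind[sub$source_name] == "triple"
  off3 <- is_triple & !sub$compartment %in% c("plastid", "mitochondrion")
  sub$compartment[off3] <- "cytosol"
  sub
}

#' Render per-family summary tables
#'
#' One TSV per core-set family mirroring the survey table layout: factor,
#' bait markers (\code{*} major, \code{+} minors), per-species class
#' counts, and a TOTAL row equal to the column sums.
#'
#' @param assignments class assignments from \code{\link{classify_groups}}.
#' @param combined combined group table (with \code{bait_groups}
#'   attribute).
#' @param core core-set data.frame.
#' @param out_dir directory for the TSVs.
#' @return named character vector of written paths.
#' @export
render_family_tables <- function(assignments, combined, core, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bait_groups <- attr(combined, "bait_groups")
  factor_of <- setNames(core$factor_id, core$accession)
  family_of <- setNames(core$family, core$accession)
  paths <- character()
  for (fam in lex_sort(unique(core$family))) {
    rows <- list()
    for (gid in names(bait_groups)) {
      baits <- bait_groups[[gid]]
      if (!any(family_of[baits] == fam, na.rm = TRUE)) next
      sub <- assignments[assignments$group_id == gid, , drop = FALSE]
      bait <- select_bait(
        combined$protein_id[combined$group_id == gid], core)
      if (is.na(bait$major)) next
      tab <- table(sub$species, sub$class)
      counts <- as.data.frame.matrix(tab)
      flat <- setNames(as.vector(as.matrix(counts)),
                       paste(rep(rownames(counts), ncol(counts)),
                             rep(colnames(counts),
                                 each = nrow(counts)), sep = "."))
      rows[[gid]] <- c(
        list(factor_id = paste(unique(unname(
          factor_of[baits])), collapse = ";"),
          group_id = gid, major = paste0(bait$major, "*"),
          minors = paste0(paste(bait$minors, collapse = ","),
                          if (length(bait$minors)) "+" else "")),
        as.list(flat))
    }
    if (length(rows) == 0L) {
      message("[vesitra] family with no groups omitted: ", fam)
      next
    }
    cols <- unique(unlist(lapply(rows, names)))
    df <- do.call(rbind, lapply(rows, function(r) {
      r[setdiff(cols, names(r))] <- 0
      as.data.frame(r[cols], stringsAsFactors = FALSE)
    }))
    numcols <- setdiff(cols, c("factor_id", "group_id", "major", "minors"))
    total <- df[1L, , drop = FALSE]
    total$factor_id <- "TOTAL"
    total$group_id <- ""
    total$major <- ""
    total$minors <- ""
    for (nc in numcols) total[[nc]] <- sum(df[[nc]])
    df <- rbind(df, total)
    rownames(df) <- NULL
    path <- file.path(out_dir,
                      paste0("family_", gsub("[^A-Za-z0-9]+", "_", fam),
                             ".tsv"))
    write_tsv_prov(df, path)
    paths[[fam]] <- path
  }
  paths
}
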