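#' Compartment vocabulary
#'
#' The eleven subcellular compartments used by the localization modules,
#' plus the merged \code{"endomembranes"} category produced in the
#' low-certainty tier.
#'
#' @export
COMPARTMENTS <- c("extracellular", "nucleus", "golgi", "er",
                  "mitochondrion", "plastid", "plasma_membrane",
                  "peroxisome", "vacuole", "cytosol", "cytoskeleton")

ENDOMEMBRANE_SET <- c("vacuole", "er", "golgi", "plasma_membrane")

# plurality over a vector of compartment votes; ties keep all maximal
# compartments (reported slash-joined, mirroring dual calls like
# "plastid/mitochondrion").
plurality_call <- function(votes, certainty) {
  if (length(votes) == 0L) {
    return(list(compartments = "unknown", votes_for = 0L, votes_total = 0L,
                certainty = certainty))
  }
  tab <- table(votes)
  best <- max(tab)
  winners <- lex_sort(names(tab)[tab == best])
  list(compartments = paste(winners, collapse = "/"),
       votes_for = as.integer(best),
       votes_total = length(votes),
       certainty = certainty)
}

check_vocabulary <- function(compartment) {
  bad <- setdiff(unique(compartment),
                 c(COMPARTMENTS, "endomembranes", "none"))
  if (length(bad) > 0L) {
    stop("unknown compartment label(s): ", paste(bad, collapse = ", "))
  }
}

#' High-certainty localization consensus for one protein
#'
#' If any experimental or literature evidence exists, the consensus is the
#' plurality over those records alone -- predictor calls can never override
#' experimental evidence. Otherwise the plurality over the (20-tool tier)
#' predictor calls is used. Ties produce multi-compartment calls; support is
#' reported as votes-for of votes-total.
#'
#' @param evidence data.frame of experimental/literature records for one
#'   protein: columns \code{compartment}, \code{source_kind} (one of
#'   \code{experimental_gfp}, \code{experimental_ms}, \code{literature}),
#'   \code{source_name}. May have zero rows.
#' @param predictor_calls data.frame of predictor records (same columns,
#'   \code{source_kind = "predictor"}). May have zero rows.
#' @return list: \code{compartments} (slash-joined string),
#'   \code{votes_for}, \code{votes_total}, \code{certainty = "high"}.
#' @export
consensus_high <- function(evidence, predictor_calls) {
  check_vocabulary(c(evidence$compartment, predictor_calls$compartment))
  if (nrow(evidence) > 0L) {
    return(plurality_call(evidence$compartment, "high"))
  }
  plurality_call(predictor_calls$compartment, "high")
}

#' Low-certainty localization consensus for one protein
#'
#' Voting over the reduced six-tool tier. Calls from the 11-compartment
#' tools that land in the vacuole/ER/Golgi/plasma-membrane set are relabeled
#' \code{"endomembranes"} before voting; single-compartment specialist tools
#' contribute a vote only when positive (a \code{"none"} call is dropped).
#' The plurality rule then matches the high tier.
#'
#' @param predictor_calls data.frame with columns \code{compartment},
#'   \code{source_name}; \code{source_name} must appear in \code{roster}.
#' @param roster data.frame describing the tier tools: columns \code{tool},
#'   \code{kind} (\code{multi11}, \code{triple} or \code{single}). Defaults
#'   to the bundled six-tool roster.
#' @return list as for \code{\link{consensus_high}}, with
#'   \code{certainty = "low"}.
#' @export
consensus_low <- function(predictor_calls,
                          roster = default_low_tier_roster()) {
  check_vocabulary(predictor_calls$compartment)
  unknown <- setdiff(predictor_calls$source_name, roster$tool)
  if (length(unknown) > 0L) {
    stop("predictor(s) not in the low tier roster: ",
         paste(unknown, collapse = ", "))
  }
  kind <- setNames(roster$kind, roster$tool)[predictor_calls$source_name]
  comp <- predictor_calls$compartment
  merge_me <- kind == "multi11" & comp %in% ENDOMEMBRANE_SET
  comp[merge_me] <- "endomembranes"
  keep <- !(kind == "single" & comp == "none")
  plurality_call(comp[keep], "low")
}

#' Bundled low-certainty predictor roster
#'
#' Six tools: two 11-compartment predictors, two three-class targeting
#' predictors and two single-compartment specialists (mitochondrion,
#' plastid), read from the package configuration file.
#'
#' @return data.frame with columns \code{tool}, \code{kind},
#'   \code{target}.
#' @export
default_low_tier_roster <- function() {
  read_tsv_plain(system.file("extdata", "predictors_low_tier.tsv",
                             package = "vesitra", mustWork = TRUE))
}

#' Bundled high-certainty predictor roster
#'
#' Names of the twenty predictors forming the high-certainty fallback tier.
#' The identities are configuration data (synthetic stand-in names), not
#' code.
#'
#' @return character vector of tool names.
#' @export
default_high_tier_roster <- function() {
  read_tsv_plain(system.file("extdata", "predictors_high_tier.tsv",
                             package = "vesitra", mustWork = TRUE))$tool
}

#' Consensus calls for a table of proteins
#'
#' Applies \code{\link{consensus_high}} or \code{\link{consensus_low}}
#' per protein over long-format evidence/prediction tables.
#'
#' @param evidence data.frame (\code{protein_id}, \code{compartment},
#'   \code{source_kind}, \code{source_name}); experimental/literature rows
#'   are used by the high tier, predictor rows by both tiers.
#' @param tier \code{"high"} or \code{"low"}.
#' @param proteins optional character vector forcing an output row (possibly
#'   \code{"unknown"}) for every listed protein.
#' @param roster low-tier roster (see \code{\link{consensus_low}}).
#' @return data.frame: \code{protein_id}, \code{compartments},
#'   \code{votes_for}, \code{votes_total}, \code{certainty}.
#' @export
consensus_calls <- function(evidence, tier = c("high", "low"),
                            proteins = NULL,
                            roster = default_low_tier_roster()) {
  tier <- match.arg(tier)
  proteins <- lex_sort(unique(c(proteins, evidence$protein_id)))
  rows <- lapply(proteins, function(p) {
    ev <- evidence[evidence$protein_id == p, , drop = FALSE]
    call <- if (tier == "high") {
      consensus_high(ev[ev$source_kind != "predictor", , drop = FALSE],
                     ev[ev$source_kind == "predictor", , drop = FALSE])
    } else {
      consensus_low(ev[ev$source_kind == "predictor", , drop = FALSE],
                    roster = roster)
    }
    data.frame(protein_id = p, compartments = call$compartments,
               votes_for = call$votes_for, votes_total = call$votes_total,
               certainty = call$certainty, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(protein_id = character(), compartments = character(),
                      votes_for = integer(), votes_total = integer(),
                      certainty = character(), stringsAsFactors = FALSE)
  }
  out
}

call_contains <- function(compartments, compartment) {
  vapply(strsplit(compartments, "/", fixed = TRUE),
         function(x) compartment %in% x, TRUE)
}

#' Cross-species compartment counts per factor
#'
#' For each factor, counts in how many plant species at least one member of
#' the factor's combined group(s) has a consensus call containing the given
#' compartment; factors supported in at least \code{flag_threshold} species
#' are flagged (the "7 or more of 14" convention).
#'
#' @param groups combined group table (\code{group_id}, \code{protein_id},
#'   \code{species}).
#' @param bait_groups named list mapping group ids to their bait accessions
#'   (as attached by \code{\link{combine_orthogroups}}).
#' @param calls consensus table from \code{\link{consensus_calls}}.
#' @param core core-set data.frame (\code{factor_id}, \code{accession}).
#' @param compartment compartment to count (vocabulary value).
#' @param plant_species character vector of plant species labels.
#' @param flag_threshold flag factors with count at or above this
#'   (default 7).
#' @return data.frame: \code{factor_id}, \code{n_species},
#'   \code{n_total}, \code{support} ("n of N"), \code{flagged}.
#' @export
cross_species_count <- function(groups, bait_groups, calls, core,
                                compartment, plant_species,
                                flag_threshold = 7L) {
  stopifnot(compartment %in% c(COMPARTMENTS, "endomembranes"))
  has_comp <- setNames(call_contains(calls$compartments, compartment),
                       calls$protein_id)
  factor_of_bait <- setNames(core$factor_id, core$accession)
  out <- list()
  for (fid in lex_sort(unique(core$factor_id))) {
    accs <- core$accession[core$factor_id == fid]
    gids <- names(bait_groups)[vapply(bait_groups, function(b)
      any(b %in% accs), TRUE)]
    mem <- groups[groups$group_id %in% gids &
                    groups$species %in% plant_species, , drop = FALSE]
    hit <- mem[!is.na(has_comp[mem$protein_id]) &
                 has_comp[mem$protein_id], , drop = FALSE]
    n <- length(unique(hit$species))
    out[[fid]] <- data.frame(
      factor_id = fid, n_species = n,
      n_total = length(plant_species),
      support = sprintf("%d of %d", n, length(plant_species)),
      flagged = n >= flag_threshold,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}
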