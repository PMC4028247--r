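#' Bundled survey summary counts
#'
#' Printed summary counts of the curated vesicle-transport factor survey
#' (per-family core-set sizes, per-source-species counts with their
#' overlap, per-species three-species (co-)orthologue totals and the
#' class-I numerator/denominator), shipped as a plain-text fixture.
#'
#' @return data.frame with columns \code{section}, \code{key}, \code{n}.
#' @export
survey_counts <- function() {
  read_tsv_plain(system.file("extdata", "survey_counts.tsv",
                             package = "vesitra", mustWork = TRUE))
}

#' Bundled tethering-factor count matrix
#'
#' Per-factor (co-)orthologue counts for the 45 tethering factors across
#' yeast, A. thaliana and S. lycopersicum, as used by
#' \code{\link{conservation_summary}}.
#'
#' @return data.frame with columns \code{factor_id}, \code{species},
#'   \code{n}.
#' @export
tethering_counts <- function() {
  read_tsv_plain(system.file("extdata", "tethering_counts.tsv",
                             package = "vesitra", mustWork = TRUE))
}

section_counts <- function(counts, section) {
  setNames(counts$n[counts$section == section],
           counts$key[counts$section == section])
}

#' Core-set arithmetic from the survey counts
#'
#' Recomputes the core-set size two independent ways: as the sum of the
#' seven per-family counts, and as the sum of the per-source-species
#' counts minus their overlap.
#'
#' @param counts data.frame from \code{\link{survey_counts}}.
#' @return list with \code{by_family}, \code{by_species} (both the
#'   core-set size), and \code{pre_overlap_total}.
#' @export
core_set_arithmetic <- function(counts = survey_counts()) {
  fam <- section_counts(counts, "family")
  spc <- section_counts(counts, "species_source")
  ovl <- section_counts(counts, "overlap")
  list(by_family = sum(fam),
       pre_overlap_total = sum(spc),
       by_species = sum(spc) - sum(ovl))
}

#' Three-species (co-)orthologue total from the survey counts
#'
#' @param counts data.frame from \code{\link{survey_counts}}.
#' @return the summed (co-)orthologue count over yeast, A. thaliana and
#'   S. lycopersicum.
#' @export
three_species_total <- function(counts = survey_counts()) {
  sum(section_counts(counts, "three_species_coorthologs"))
}
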