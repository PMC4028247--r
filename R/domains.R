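#' Read a per-protein domain-hit table
#'
#' Expects a TSV with columns \code{protein_id}, \code{accession},
#' \code{name}, \code{ali_start}, \code{ali_end}, \code{evalue}. Hits are
#' sorted by alignment start per protein; when two hits overlap by more than
#' half of the shorter span, only the hit with the lower e-value is kept.
#'
#' @param path path to the TSV (header required).
#' @return named list: protein id to character vector of domain accessions
#'   in N-to-C order (empty architectures appear only for proteins listed
#'   with zero retained hits).
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) stop("domain table not found: ", path)
  df <- read_tsv_plain(path)
  need <- c("protein_id", "accession", "name", "ali_start", "ali_end",
            "evalue")
  if (!all(need %in% names(df))) {
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  }
  for (cn in c("ali_start", "ali_end", "evalue")) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v) && !all(is.na(df[[cn]]))) {
      stop("malformed domain table row ", which(is.na(v))[1L],
           ": non-numeric ", cn)
    }
    df[[cn]] <- v
  }
  archs <- lapply(split(df, df$protein_id), resolve_domain_hits)
  archs[lex_sort(names(archs))]
}

# Greedy overlap resolution: scan hits in order of increasing e-value and
# keep a hit unless it overlaps an already kept hit by >50% of the shorter
# span. Ordering of the survivors is by alignment start.
resolve_domain_hits <- function(hits) {
  hits <- hits[order(hits$evalue, hits$ali_start, hits$accession,
                     method = "radix"), , drop = FALSE]
  kept <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ok <- TRUE
    for (j in which(kept)) {
      ov <- min(hits$ali_end[i], hits$ali_end[j]) -
            max(hits$ali_start[i], hits$ali_start[j]) + 1
      shorter <- min(hits$ali_end[i] - hits$ali_start[i] + 1,
                     hits$ali_end[j] - hits$ali_start[j] + 1)
      if (ov > 0.5 * shorter) {
        ok <- FALSE
        break
      }
    }
    kept[i] <- ok
  }
  hits <- hits[kept, , drop = FALSE]
  hits <- hits[order(hits$ali_start, hits$accession, method = "radix"), ,
               drop = FALSE]
  hits$accession
}

#' Select major and minor baits for an orthologous group
#'
#' Priority order: yeast factors first, then experimentally proven
#' Arabidopsis factors, then predicted Arabidopsis factors; ties resolved by
#' lexicographic accession. All remaining core factors in the group become
#' minor baits.
#'
#' @param group_members character vector of protein ids in the group.
#' @param core core-set data.frame with columns \code{accession},
#'   \code{species} (\code{"yeast"} or \code{"arabidopsis"}),
#'   \code{evidence} (\code{"experimental"} or \code{"predicted"}).
#' @return list with \code{major} (accession or \code{NA} when the group
#'   has no core member) and \code{minors} (character vector).
#' @export
select_bait <- function(group_members, core) {
  inset <- core[core$accession %in% group_members, , drop = FALSE]
  if (nrow(inset) == 0L) {
    return(list(major = NA_character_, minors = character()))
  }
  rank <- ifelse(inset$species == "yeast", 1L,
          ifelse(inset$evidence == "experimental", 2L, 3L))
  inset <- inset[order(rank, inset$accession, method = "radix"), ,
                 drop = FALSE]
  accs <- unique(inset$accession)
  list(major = accs[1L], minors = accs[-1L])
}

#' Classify a member architecture against the bait architecture
#'
#' Class I: the ordered accession lists are identical (including repeat
#' counts; two empty architectures are vacuously identical). Class III: the
#' accession sets are disjoint, including the case where exactly one side
#' has no domains. Class II: everything in between -- at least one shared
#' accession but a non-identical list, covering both gained and lost
#' domains.
#'
#' @param member,bait character vectors of ordered domain accessions.
#' @param collapse_repeats collapse consecutive repeats of the same
#'   accession before comparison (default \code{FALSE}).
#' @return \code{"I"}, \code{"II"} or \code{"III"}.
#' @export
classify_architecture <- function(member, bait, collapse_repeats = FALSE) {
  member <- as.character(member %||% character())
  bait <- as.character(bait %||% character())
  if (collapse_repeats) {
    member <- rle(member)$values
    bait <- rle(bait)$values
  }
  if (length(member) == length(bait) && all(member == bait)) return("I")
  if (length(intersect(member, bait)) == 0L) return("III")
  "II"
}

#' Classify all members of combined groups against their major baits
#'
#' Groups without any core-set member are reported as unassigned and
#' excluded from classification; the major bait itself is not classified
#' against itself (it would trivially be class I) but minor baits and all
#' other members are.
#'
#' @param groups combined group table (\code{group_id}, \code{protein_id},
#'   \code{species}).
#' @param archs named list of architectures (from
#'   \code{\link{read_domain_table}}); proteins missing from the list are
#'   treated as having no detected domains.
#' @param core core-set data.frame.
#' @param include_bait also emit a class-I row for the major bait itself
#'   (default \code{FALSE}).
#' @param collapse_repeats passed to \code{\link{classify_architecture}}.
#' @return list with \code{assignments} (data.frame: group_id, protein_id,
#'   species, bait, class) and \code{unassigned} (character vector of group
#'   ids with no core member).
#' @export
classify_groups <- function(groups, archs, core, include_bait = FALSE,
                            collapse_repeats = FALSE) {
  get_arch <- function(p) archs[[p]] %||% character()
  out <- list()
  unassigned <- character()
  for (gid in unique(groups$group_id)) {
    sub <- groups[groups$group_id == gid, , drop = FALSE]
    bait <- select_bait(sub$protein_id, core)
    if (is.na(bait$major)) {
      unassigned <- c(unassigned, gid)
      next
    }
    bait_arch <- get_arch(bait$major)
    targets <- if (include_bait) sub$protein_id else
      setdiff(sub$protein_id, bait$major)
    if (length(targets) == 0L) next
    cls <- vapply(targets, function(p) {
      classify_architecture(get_arch(p), bait_arch,
                            collapse_repeats = collapse_repeats)
    }, "")
    out[[gid]] <- data.frame(
      group_id = gid,
      protein_id = targets,
      species = sub$species[match(targets, sub$protein_id)],
      bait = bait$major,
      class = unname(cls),
      stringsAsFactors = FALSE)
  }
  assignments <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(group_id = character(), protein_id = character(),
               species = character(), bait = character(),
               class = character(), stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  list(assignments = assignments, unassigned = unassigned)
}

#' Summarize architecture classes
#'
#' Counts class assignments per species and class (and per family when the
#' core table carries one for the group's bait) and reports the overall
#' class-I fraction.
#'
#' @param assignments data.frame from \code{\link{classify_groups}}.
#' @param core optional core-set data.frame with \code{accession} and
#'   \code{family}; when supplied, rows are attributed to the family of the
#'   group's major bait.
#' @return list with \code{table} (family x species x class counts, long
#'   format), \code{class1_fraction} (percentage with one decimal, or
#'   \code{NA} for empty input), \code{class1_percent_rounded} (integer
#'   percent) and \code{totals} (named class counts).
#' @export
summarize_classes <- function(assignments, core = NULL) {
  if (nrow(assignments) == 0L) {
    return(list(table = data.frame(family = character(),
                                   species = character(),
                                   class = character(),
                                   n = integer(), stringsAsFactors = FALSE),
                class1_fraction = NA_real_,
                class1_percent_rounded = NA_integer_,
                totals = c(I = 0L, II = 0L, III = 0L)))
  }
  fam <- rep("all", nrow(assignments))
  if (!is.null(core) && "family" %in% names(core)) {
    fmap <- setNames(core$family, core$accession)
    fam <- unname(fmap[assignments$bait])
    fam[is.na(fam)] <- "unknown"
  }
  tab <- as.data.frame(table(family = fam, species = assignments$species,
                             class = assignments$class),
                       stringsAsFactors = FALSE)
  names(tab)[4L] <- "n"
  tab <- tab[tab$n > 0L, , drop = FALSE]
  rownames(tab) <- NULL
  totals <- c(I = sum(assignments$class == "I"),
              II = sum(assignments$class == "II"),
              III = sum(assignments$class == "III"))
  frac <- class1_fraction(totals[["I"]], nrow(assignments))
  list(table = tab, class1_fraction = frac$one_decimal,
       class1_percent_rounded = frac$rounded, totals = totals)
}

#' Class-I fraction from a numerator and denominator
#'
#' @param n_class1 number of class-I members.
#' @param n_total total classified members.
#' @return list with \code{one_decimal} (percent, one decimal) and
#'   \code{rounded} (integer percent).
#' @export
class1_fraction <- function(n_class1, n_total) {
  if (n_total == 0L) {
    return(list(one_decimal = NA_real_, rounded = NA_integer_))
  }
  pct <- 100 * n_class1 / n_total
  list(one_decimal = round(pct, 1L), rounded = as.integer(round(pct)))
}

#' Presence/absence conservation summary
#'
#' From per-factor, per-species member counts, flags factors found in a
#' single species only (e.g. tethering factors confined to yeast) and
#' factors absent everywhere.
#'
#' @param counts data.frame with columns \code{factor_id}, \code{species},
#'   \code{n} (summed over all groups of that factor).
#' @return list with \code{presence} (factor x species 0/1 matrix),
#'   \code{single_species} (data.frame factor_id, species) and
#'   \code{absent} (character vector).
#' @export
conservation_summary <- function(counts) {
  stopifnot(all(c("factor_id", "species", "n") %in% names(counts)))
  agg <- tapply(counts$n, list(counts$factor_id, counts$species), sum)
  agg[is.na(agg)] <- 0
  presence <- (agg > 0) * 1L
  npresent <- rowSums(presence)
  single <- which(npresent == 1L)
  single_species <- data.frame(
    factor_id = rownames(presence)[single],
    species = colnames(presence)[apply(
      presence[single, , drop = FALSE], 1L, which.max)],
    stringsAsFactors = FALSE)
  rownames(single_species) <- NULL
  list(presence = presence,
       single_species = single_species,
       absent = rownames(presence)[npresent == 0L])
}
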