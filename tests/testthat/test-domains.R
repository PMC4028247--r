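dom_tsv <- function(rows) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

dom_row <- function(protein_id, accession, start, end, evalue) {
  data.frame(protein_id = protein_id, accession = accession,
             name = tolower(accession), ali_start = start, ali_end = end,
             evalue = evalue, stringsAsFactors = FALSE)
}

test_that("read_domain_table orders hits and resolves overlaps", {
  f <- dom_tsv(rbind(
    dom_row("p1", "PFB", 100, 150, 1e-10),
    dom_row("p1", "PFA", 5, 60, 1e-12),
    dom_row("p2", "PFGOOD", 10, 60, 1e-30),   # full overlap, better e-value
    dom_row("p2", "PFBAD", 10, 60, 1e-3),
    dom_row("p3", "PFX", 1, 100, 1e-20),      # 30% overlap of shorter: keep
    dom_row("p3", "PFY", 86, 135, 1e-4)))
  archs <- read_domain_table(f)
  expect_equal(archs$p1, c("PFA", "PFB"))
  expect_equal(archs$p2, "PFGOOD")
  expect_equal(archs$p3, c("PFX", "PFY"))
})

test_that("read_domain_table rejects malformed rows", {
  f <- dom_tsv(dom_row("p1", "PFA", "oops", 60, 1e-12))
  expect_error(read_domain_table(f), "non-numeric")
  expect_error(read_domain_table(file.path(tempdir(), "none.tsv")),
               "not found")
})

test_that("select_bait follows the species/evidence priority", {
  core <- data.frame(
    factor_id = c("f1", "f2", "f3", "f4", "f5"),
    family = "COP-II",
    species = c("yeast", "arabidopsis", "arabidopsis", "yeast",
                "arabidopsis"),
    accession = c("Yb", "AeX", "ApZ", "Ya", "AeY"),
    evidence = c("experimental", "experimental", "predicted",
                 "experimental", "experimental"),
    stringsAsFactors = FALSE)
  # yeast beats arabidopsis-experimental
  b1 <- select_bait(c("Yb", "AeX", "other"), core)
  expect_equal(b1$major, "Yb")
  expect_equal(b1$minors, "AeX")
  # predicted-only group: the predicted factor is major
  b2 <- select_bait(c("ApZ", "other"), core)
  expect_equal(b2$major, "ApZ")
  # two yeast factors: lexicographic accession
  b3 <- select_bait(c("Yb", "Ya"), core)
  expect_equal(b3$major, "Ya")
  # arabidopsis experimental beats predicted
  b4 <- select_bait(c("ApZ", "AeY"), core)
  expect_equal(b4$major, "AeY")
  # no core member
  expect_true(is.na(select_bait(c("other"), core)$major))
})

test_that("classify_architecture reproduces the worked examples", {
  # identical ordered lists
  expect_equal(classify_architecture(c("PF00071"), c("PF00071")), "I")
  # member gains a C-terminal coatomer-beta domain
  expect_equal(classify_architecture(c("PF01602", "PF07718"),
                                     c("PF01602")), "II")
  # member lost the N-terminal domain of a three-domain bait
  expect_equal(classify_architecture(c("PF12932", "PF12931"),
                                     c("PF12935", "PF12932", "PF12931")),
               "II")
  # entirely different architectures
  expect_equal(classify_architecture(c("PF05002"), c("PF00626")), "III")
  # one side empty is disjoint; both empty is vacuous identity
  expect_equal(classify_architecture(character(), c("PF1")), "III")
  expect_equal(classify_architecture(character(), character()), "I")
  # same set, different order is II, and repeats matter
  expect_equal(classify_architecture(c("A", "B"), c("B", "A")), "II")
  expect_equal(classify_architecture(c("A", "A"), c("A")), "II")
  expect_equal(classify_architecture(c("A", "A"), c("A"),
                                     collapse_repeats = TRUE), "I")
})

test_that("classify_architecture matches a brute-force oracle", {
  oracle <- function(m, b) {
    if (identical(as.character(m), as.character(b))) return("I")
    shared <- FALSE
    for (x in m) for (y in b) if (x == y) shared <- TRUE
    if (shared) "II" else "III"
  }
  set.seed(13)
  alphabet <- paste0("D", 1:10)
  for (i in 1:1000) {
    m <- sample(alphabet, sample(0:5, 1), replace = TRUE)
    b <- sample(alphabet, sample(0:5, 1), replace = TRUE)
    expect_identical(classify_architecture(m, b), oracle(m, b))
  }
  # reflexivity and III symmetry on random pairs
  set.seed(14)
  for (i in 1:50) {
    m <- sample(alphabet, sample(1:5, 1), replace = TRUE)
    b <- sample(alphabet, sample(1:5, 1), replace = TRUE)
    expect_identical(classify_architecture(m, m), "I")
    expect_identical(classify_architecture(m, b) == "III",
                     classify_architecture(b, m) == "III")
  }
})

test_that("classify_groups classifies members against the major bait", {
  groups <- data.frame(
    group_id = "g1",
    protein_id = c("Ya", "m1", "m2", "m3"),
    species = c("yeast", "plant", "plant", "plant"),
    stringsAsFactors = FALSE)
  core <- data.frame(factor_id = "f", family = "SNARE", species = "yeast",
                     accession = "Ya", evidence = "experimental",
                     stringsAsFactors = FALSE)
  archs <- list(Ya = c("PF1", "PF2"), m1 = c("PF1", "PF2"),
                m2 = c("PF1"), m3 = c("PF9"))
  out <- classify_groups(groups, archs, core)
  cls <- setNames(out$assignments$class, out$assignments$protein_id)
  expect_equal(unname(cls[c("m1", "m2", "m3")]), c("I", "II", "III"))
  expect_false("Ya" %in% names(cls))
  expect_equal(unique(out$assignments$bait), "Ya")

  # group without core member is reported unassigned
  g2 <- data.frame(group_id = "g2", protein_id = "x", species = "plant",
                   stringsAsFactors = FALSE)
  out2 <- classify_groups(g2, archs, core)
  expect_equal(out2$unassigned, "g2")
  expect_equal(nrow(out2$assignments), 0L)
})

test_that("summarize_classes computes fractions and conserves counts", {
  mk_assign <- function(n1, n2, n3) {
    n <- n1 + n2 + n3
    data.frame(group_id = rep("g", n),
               protein_id = paste0("p", seq_len(n)),
               species = rep("plant", n), bait = rep("b", n),
               class = rep(c("I", "II", "III"), c(n1, n2, n3)),
               stringsAsFactors = FALSE)
  }
  s <- summarize_classes(mk_assign(416, 100, 11))
  expect_equal(sum(s$totals), 527)
  expect_equal(s$class1_fraction, 78.9)
  expect_equal(s$class1_percent_rounded, 79L)
  expect_equal(sum(s$table$n), 527)

  all1 <- summarize_classes(mk_assign(10, 0, 0))
  expect_equal(all1$class1_fraction, 100)

  emp <- summarize_classes(mk_assign(1, 0, 0)[0, , drop = FALSE])
  expect_true(is.na(emp$class1_fraction))
})

test_that("class1_fraction reproduces the printed percentage", {
  f <- class1_fraction(416, 527)
  expect_equal(f$one_decimal, 78.9)
  expect_equal(f$rounded, 79L)
  expect_true(is.na(class1_fraction(0, 0)$one_decimal))
})

test_that("conservation_summary flags single-species and absent factors", {
  counts <- data.frame(
    factor_id = rep(c("everywhere", "yeastonly", "ghost"), each = 3),
    species = rep(c("yeast", "arabidopsis", "tomato"), 3),
    n = c(1, 2, 1, 1, 0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
  cons <- conservation_summary(counts)
  expect_equal(cons$single_species$factor_id, "yeastonly")
  expect_equal(cons$single_species$species, "yeast")
  expect_equal(cons$absent, "ghost")
  expect_equal(cons$presence["everywhere", ],
               c(arabidopsis = 1L, tomato = 1L, yeast = 1L))
})
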