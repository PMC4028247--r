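two_species <- function(ids_a, ids_b) {
  data.frame(id = c(ids_a, ids_b),
             species = c(rep("A", length(ids_a)), rep("B", length(ids_b))),
             stringsAsFactors = FALSE)
}

test_that("build_graph filters, weights and averages reciprocal hits", {
  prot <- two_species(c("a1", "a2"), c("b1"))
  hits <- rbind(
    hits_from_weights(data.frame(a = "a1", b = "b1", w = 5)),
    hits_from_weights(data.frame(a = "b1", b = "a1", w = 7)),  # reciprocal
    hits_from_weights(data.frame(a = "a2", b = "b1", w = 3)))  # above cutoff
  g <- build_graph(hits, prot, cutoff = 1e-5)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$w, 6)            # mean of 5 and 7
  expect_equal(g$edges$category, "inter")

  g0 <- build_graph(hits_from_weights(data.frame(a = "a1", b = "b1",
                                                 w = 200)),
                    prot, cutoff = 1e-5)
  expect_equal(g0$edges$w, 180)         # capped at the e-value floor

  expect_error(build_graph(hits_from_weights(
    data.frame(a = "zz", b = "b1", w = 9)), prot), "unknown protein")
})

test_that("normalize_weights divides by the stratum mean", {
  prot <- two_species(c("a1", "a2"), c("b1", "b2"))
  edges <- data.frame(a = c("a1", "a2"), b = c("b1", "b2"), w = c(4, 8))
  g <- normalize_weights(graph_from_weights(edges, prot))
  expect_equal(sort(g$edges$w), c(4 / 6, 8 / 6), tolerance = 1e-12)

  single <- normalize_weights(graph_from_weights(
    data.frame(a = "a1", b = "b1", w = 17), prot))
  expect_equal(single$edges$w, 1)

  equalw <- normalize_weights(graph_from_weights(
    data.frame(a = c("a1", "a2"), b = c("b1", "b2"), w = c(5, 5)), prot))
  expect_equal(equalw$edges$w, c(1, 1))
})

test_that("normalization is stratified by species pair and category", {
  prot <- data.frame(id = c("a1", "a2", "b1", "b2"),
                     species = c("A", "A", "B", "B"),
                     stringsAsFactors = FALSE)
  edges <- data.frame(a = c("a1", "a1"), b = c("a2", "b1"), w = c(10, 2))
  g <- normalize_weights(graph_from_weights(edges, prot))
  # each edge is alone in its stratum (intra-A vs inter-AB) -> both 1
  expect_equal(g$edges$w, c(10 / 10, 2 / 2))
})

test_that("mcl separates components and isolated nodes", {
  prot <- data.frame(id = paste0("p", 1:7),
                     species = "A", stringsAsFactors = FALSE)
  tri <- function(x, y, z) data.frame(a = c(x, x, y), b = c(y, z, z),
                                      w = 1)
  edges <- rbind(tri("p1", "p2", "p3"), tri("p4", "p5", "p6"))
  g <- graph_from_weights(edges, prot)   # p7 isolated
  out <- mcl(g, inflation = 2)
  grp <- setNames(out$group_id, out$protein_id)
  expect_equal(length(unique(grp)), 3L)
  expect_equal(length(unique(grp[c("p1", "p2", "p3")])), 1L)
  expect_equal(length(unique(grp[c("p4", "p5", "p6")])), 1L)
  expect_false(grp[["p1"]] == grp[["p4"]])
  expect_equal(sum(out$protein_id == "p7"), 1L)
  # partition: every node in exactly one group
  expect_setequal(out$protein_id, prot$id)
  expect_equal(anyDuplicated(out$protein_id), 0L)
})

test_that("mcl splits a weakly bridged barbell", {
  prot <- data.frame(id = paste0("p", 1:6), species = "A",
                     stringsAsFactors = FALSE)
  edges <- data.frame(
    a = c("p1", "p1", "p2", "p4", "p4", "p5", "p3"),
    b = c("p2", "p3", "p3", "p5", "p6", "p6", "p4"),
    w = c(1, 1, 1, 1, 1, 1, 0.1))
  out <- mcl(graph_from_weights(edges, prot), inflation = 2)
  grp <- setNames(out$group_id, out$protein_id)
  expect_equal(length(unique(grp)), 2L)
  expect_equal(length(unique(grp[c("p1", "p2", "p3")])), 1L)
  expect_equal(length(unique(grp[c("p4", "p5", "p6")])), 1L)
})

test_that("mcl agrees with an independent matrix-iteration oracle", {
  set.seed(2601)
  for (trial in 1:12) {
    n <- sample(4:8, 1)
    rg <- random_small_graph(n)
    out <- mcl(rg$graph, inflation = 2)
    W <- adjacency_from_edges(rg$edges, rg$proteins$id)
    oracle <- mcl_oracle(W, inflation = 2)
    got <- setNames(out$group_id, out$protein_id)[rg$proteins$id]
    expect_equal(adjusted_rand_index(got, oracle), 1)
  }
})

test_that("mcl never merges nodes from different connected components", {
  set.seed(77)
  for (trial in 1:5) {
    rg1 <- random_small_graph(5)
    ids2 <- sprintf("q%02d", 1:5)
    prot <- rbind(rg1$proteins,
                  data.frame(id = ids2, species = "s3",
                             stringsAsFactors = FALSE))
    edges2 <- rg1$edges
    edges2$a <- sub("^p", "q", edges2$a)
    edges2$b <- sub("^p", "q", edges2$b)
    g <- graph_from_weights(rbind(rg1$edges, edges2), prot)
    out <- mcl(g)
    grp <- setNames(out$group_id, out$protein_id)
    expect_equal(length(intersect(grp[grepl("^p", names(grp))],
                                  grp[grepl("^q", names(grp))])), 0L)
  }
})

test_that("reciprocal_best_hits finds mutual best partners", {
  prot <- two_species("a", "b")
  g1 <- graph_from_weights(data.frame(a = "a", b = "b", w = 5), prot)
  expect_equal(reciprocal_best_hits(g1, "A", "B"),
               data.frame(a = "a", b = "b", seed_weight = 5,
                          stringsAsFactors = FALSE))

  prot2 <- two_species("a", c("b1", "b2"))
  g2 <- graph_from_weights(
    data.frame(a = c("a", "a"), b = c("b1", "b2"), w = c(5, 7)), prot2)
  seeds <- reciprocal_best_hits(g2, "A", "B")
  expect_equal(seeds$b, "b2")
  expect_equal(nrow(seeds), 1L)

  # tie -> lexicographically smaller partner
  g3 <- graph_from_weights(
    data.frame(a = c("a", "a"), b = c("b2", "b1"), w = c(6, 6)), prot2)
  expect_equal(reciprocal_best_hits(g3, "A", "B")$b, "b1")

  # no cross edges -> empty
  g4 <- graph_from_weights(data.frame(a = "b1", b = "b2", w = 3), prot2)
  expect_equal(nrow(reciprocal_best_hits(g4, "A", "B")), 0L)
})

test_that("expand_in_paralogs applies the >= seed-weight rule", {
  prot <- data.frame(id = c("a", "a2", "a3", "a4", "b"),
                     species = c("A", "A", "A", "A", "B"),
                     stringsAsFactors = FALSE)
  g <- graph_from_weights(data.frame(
    a = c("a", "a", "a", "a"),
    b = c("b", "a2", "a3", "a4"),
    w = c(5, 7, 4, 5)), prot)
  seed <- reciprocal_best_hits(g, "A", "B")
  members <- expand_in_paralogs(seed, g)
  expect_setequal(members, c("a", "b", "a2", "a4"))  # 7 and 5 in, 4 out
})

test_that("merge_pairwise_groups is a transitive union", {
  nodes <- data.frame(id = letters[1:6], species = "A",
                      stringsAsFactors = FALSE)
  out <- merge_pairwise_groups(
    list(c("a", "b"), c("b", "c"), c("c", "d"), c("e", "f")), nodes)
  grp <- setNames(out$group_id, out$protein_id)
  expect_equal(length(unique(grp[c("a", "b", "c", "d")])), 1L)
  expect_equal(length(unique(grp)), 2L)
  expect_false(grp[["a"]] == grp[["e"]])
  # disjoint groups stay unchanged
  out2 <- merge_pairwise_groups(list(c("a", "b"), c("c", "d")), nodes)
  expect_equal(length(unique(out2$group_id)), 2L)
})

test_that("combine_orthogroups unions per bait and resolves conflicts", {
  prot <- data.frame(id = c("bait1", "bait2", "x", "y"),
                     species = c("A", "A", "B", "B"),
                     stringsAsFactors = FALSE)
  g <- graph_from_weights(data.frame(
    a = c("bait1", "bait2", "bait1"),
    b = c("x", "x", "y"),
    w = c(6, 4, 5)), prot)
  core <- data.frame(factor_id = c("f1", "f2"), family = "COP-II",
                     species = "yeast",
                     accession = c("bait1", "bait2"),
                     evidence = "experimental", stringsAsFactors = FALSE)
  mk <- function(sets, source) {
    comp <- unlist(lapply(seq_along(sets), function(i)
      setNames(rep(i, length(sets[[i]])), sets[[i]])))
    vesitra:::groups_from_membership(comp, prot, source)
  }
  # algorithm 1 groups {bait1,x}; algorithm 2 groups {bait1,y}: union
  mcl_set <- mk(list(c("bait1", "x"), "bait2", "y"), "mcl")
  par_set <- mk(list(c("bait1", "y"), "bait2", "x"), "paranoid")
  comb <- combine_orthogroups(mcl_set, par_set, core, g)
  g1 <- comb$protein_id[comb$group_id ==
                          comb$group_id[comb$protein_id == "bait1"]]
  expect_setequal(g1, c("bait1", "x", "y"))

  # both algorithms agree -> combined equals either
  same <- mk(list(c("bait1", "x"), c("bait2", "y")), "mcl")
  same2 <- mk(list(c("bait1", "x"), c("bait2", "y")), "paranoid")
  comb2 <- combine_orthogroups(same, same2, core, g)
  expect_setequal(
    comb2$protein_id[comb2$group_id ==
                       comb2$group_id[comb2$protein_id == "bait1"]],
    c("bait1", "x"))

  # x claimed by both baits -> goes to bait1 (w 6 > 4), no ambiguity
  mcl3 <- mk(list(c("bait1", "x"), "bait2", "y"), "mcl")
  par3 <- mk(list(c("bait2", "x"), "bait1", "y"), "paranoid")
  comb3 <- combine_orthogroups(mcl3, par3, core, g)
  x_groups <- comb3$group_id[comb3$protein_id == "x"]
  expect_equal(length(x_groups), 1L)
  expect_true("bait1" %in% comb3$protein_id[comb3$group_id == x_groups])
  expect_false(any(comb3$ambiguous))

  expect_error(combine_orthogroups(mcl_set, par_set,
                                   data.frame(accession = "ghost"), g),
               "ghost")
})

test_that("combine keeps every member either algorithm placed with a bait", {
  set.seed(909)
  for (trial in 1:5) {
    n <- 10
    rg <- random_small_graph(n)
    g <- graph_from_weights(rg$edges, rg$proteins)
    core <- data.frame(factor_id = "f1", family = "SNARE",
                       species = "yeast", accession = "p01",
                       evidence = "experimental", stringsAsFactors = FALSE)
    part <- function(seed0, source) {
      set.seed(seed0)
      comp <- sample(1:3, n, replace = TRUE)
      vesitra:::groups_from_membership(setNames(comp, rg$proteins$id),
                                       rg$proteins, source)
    }
    m <- part(trial, "mcl")
    p <- part(trial + 100, "paranoid")
    comb <- combine_orthogroups(m, p, core, g)
    with_bait <- union(
      m$protein_id[m$group_id == m$group_id[m$protein_id == "p01"]],
      p$protein_id[p$group_id == p$group_id[p$protein_id == "p01"]])
    expect_true(all(with_bait %in% comb$protein_id))
  }
})
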