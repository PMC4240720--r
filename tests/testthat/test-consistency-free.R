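test_that("forced triplets come from induced paths with a known non-edge", {
  fam <- fam_distinct(3)
  expect_identical(nrow(extract_p3(constraint_graph(fam))), 0L)

  # b1 - e1 - c2 path with a paralogy non-edge b1c2 forces bc|e
  fam2 <- gene_family(c("b1", "c2", "e1"), c("b", "c", "e"))
  g <- constraint_graph(fam2, orthology = pairs(c("b1", "e1"), c("c2", "e1")))
  got <- extract_p3(g)
  expect_identical(orthocons:::triplet_key(got[, "x"], got[, "y"], got[, "z"]),
                   "b|c|e")
  # with the closing pair unknown instead of a non-edge, nothing is forced
  gu <- constraint_graph(fam2, orthology = pairs(c("b1", "e1"), c("c2", "e1")),
                         unknown = pairs(c("b1", "c2")))
  expect_identical(nrow(extract_p3(gu)), 0L)
  # same-species endpoints do not force a triplet
  fam3 <- gene_family(c("b1", "b2", "e1"), c("b", "b", "e"))
  g3 <- constraint_graph(fam3, orthology = pairs(c("b1", "e1"), c("b2", "e1")))
  expect_identical(nrow(extract_p3(g3)), 0L)
})

test_that("supertree assembly displays compatible triplet sets and rejects clashes", {
  t1 <- orthocons:::triplet_unkey("a|b|c")
  s1 <- build_species_tree(t1, c("a", "b", "c"))
  expect_true(displays(s1, triplet_tree("a", "b", "c")))
  t2 <- orthocons:::triplet_unkey(c("a|b|c", "a|c|b"))
  expect_null(build_species_tree(t2, c("a", "b", "c")))
  # unconstrained species attach without resolution
  s3 <- build_species_tree(t1, c("a", "b", "c", "d", "e"))
  expect_true(displays(s3, triplet_tree("a", "b", "c")))
  expect_setequal(tree_leaves(s3), c("a", "b", "c", "d", "e"))
  # a triplet with a repeated label can never be displayed
  expect_null(build_species_tree(orthocons:::triplet_unkey("a|b|a"),
                                 c("a", "b")))

  # verdict agrees with exhaustive search over all rooted species trees
  set.seed(51)
  for (rep in 1:30) {
    k <- sample(3:5, 1L)
    sp <- paste0("S", seq_len(k))
    ntr <- sample(1:4, 1L)
    trs <- t(replicate(ntr, sample(sp, 3L)))
    trip <- orthocons:::triplet_unkey(unique(
      orthocons:::triplet_key(trs[, 1L], trs[, 2L], trs[, 3L])))
    got <- build_species_tree(trip, sp)
    oracle <- any(vapply(all_rooted_trees(sp), function(st) {
      all(vapply(seq_len(nrow(trip)), function(i) {
        displays(st, triplet_tree(trip[i, "x"], trip[i, "y"], trip[i, "z"]))
      }, logical(1L)))
    }, logical(1L)))
    expect_identical(!is.null(got), oracle)
    if (!is.null(got)) {
      for (i in seq_len(nrow(trip))) {
        expect_true(displays(got, triplet_tree(trip[i, "x"], trip[i, "y"],
                                               trip[i, "z"])))
      }
    }
  }
})

test_that("adding triplets can only break displayability, never restore it", {
  set.seed(52)
  sp <- paste0("S", 1:5)
  for (rep in 1:20) {
    trs <- t(replicate(6, sample(sp, 3L)))
    keys <- unique(orthocons:::triplet_key(trs[, 1L], trs[, 2L], trs[, 3L]))
    ok_prev <- TRUE
    for (m in seq_along(keys)) {
      ok <- !is.null(build_species_tree(orthocons:::triplet_unkey(keys[1:m]), sp))
      expect_false(!ok_prev && ok)
      ok_prev <- ok
    }
  }
})

test_that("orthology-only and paralogy-only constraint sets are always consistent", {
  set.seed(53)
  for (rep in 1:25) {
    n <- sample(2:9, 1L)
    k <- sample(1:4, 1L)
    fam <- gene_family(paste0("g", seq_len(n)),
                       paste0("s", sample.int(k, n, replace = TRUE)))
    ro <- orthology_only_witness(fam)
    expect_identical(ro$status, "consistent")
    expect_true(satisfies(ro$witness, ro$realization))
    expect_true(is_consistent(ro$witness, fam, ro$species_tree))
    rp <- paralogy_only_witness(fam)
    expect_identical(rp$status, "consistent")
    expect_true(satisfies(rp$witness, rp$realization))
    expect_true(is_consistent(rp$witness, fam, rp$species_tree))
  }
  # degenerate: single species, single gene
  solo <- gene_family("g1", "sA")
  expect_identical(orthology_only_witness(solo)$status, "consistent")
  expect_identical(paralogy_only_witness(solo)$status, "consistent")
  two <- gene_family(c("g1", "g2"), c("sA", "sA"))
  expect_identical(orthology_only_witness(two)$witness$event, "D")
})

test_that("full-graph consistency equals the forced-triplet supertree test", {
  p4 <- constraint_graph(fam_distinct(4),
                         orthology = pairs(c("a", "b"), c("b", "c"), c("c", "d")))
  expect_identical(check_consistency_full(p4)$status, "inconsistent")

  res <- check_consistency_full(forced_ade_graph())
  expect_identical(res$status, "consistent")
  expect_true(displays(res$species_tree, triplet_tree("a", "d", "e")))

  # Theorem-5 route vs the DS-tree / speciation-triplet route
  set.seed(54)
  checked <- 0L
  while (checked < 60L) {
    n <- sample(4:7, 1L)
    k <- sample(2:4, 1L)
    spmap <- sample.int(k, n, replace = TRUE)
    spmap <- match(spmap, unique(spmap))
    fam <- oc_family(n, spmap)
    pm <- oc_pairs(n)
    cross <- which(spmap[pm[, 1L]] != spmap[pm[, 2L]])
    epos <- cross[stats::runif(length(cross)) < 0.45]
    g <- oc_graph(fam, oc_bits_mask(epos), 0L)
    sat <- build_ds_tree(g)
    if (sat$status != "satisfiable") next
    checked <- checked + 1L
    route_a <- check_consistency_full(g)$status == "consistent"
    trs <- speciation_triplets(sat$witness, fam)
    route_b <- !is.null(build_species_tree(trs, unique(unname(fam$species))))
    expect_identical(route_a, route_b)
  }
})

test_that("branch-and-bound handles single-unknown repairs and delegates full graphs", {
  # full graph: delegation to the forced-triplet route
  res <- check_cons(forced_ade_graph())
  expect_identical(res$status, "consistent")
  expect_true(is_full_graph(res$realization))

  # P4 in E with the single resolving chord unknown: only the orthology
  # branch survives
  fam <- fam_distinct(4)
  g <- constraint_graph(fam,
                        orthology = pairs(c("a", "b"), c("b", "c"), c("c", "d")),
                        unknown = pairs(c("a", "c")))
  both <- lapply(list(character(), g$U), function(F) {
    full <- realize(g, F)
    build_ds_tree(full)$status
  })
  expect_identical(both[[1L]], "unsatisfiable")
  expect_identical(both[[2L]], "satisfiable")
  res2 <- check_cons(g)
  expect_identical(res2$status, "consistent")
  expect_true(orthocons:::pair_key("a", "c") %in% res2$realization$E)
})

test_that("the node cap raises a typed error instead of a wrong verdict", {
  set.seed(55)
  inst <- NULL
  seed <- 200L
  repeat {
    seed <- seed + 1L
    inst <- simulate_instance(sim_config(n_species = 4, dup_prob = 0.3,
                                         loss_prob = 0.1, mask_frac = 0.5,
                                         seed = seed))
    if (length(inst$graph$U) >= 4L) break
  }
  expect_error(check_cons(inst$graph, max_nodes = 1L),
               class = "orthocons_search_limit")
})

test_that("forced-edge preprocessing fixes single-option P4 repairs", {
  fam <- fam_distinct(4)
  # identity on a graph with no unknowns
  full <- constraint_graph(fam, orthology = pairs(c("a", "b")))
  pp0 <- preprocess_forced_edges(full)
  expect_false(pp0$contradiction)
  expect_length(pp0$forced, 0L)

  # E-side P4 with one unknown chord: the chord is forced to orthology
  g <- constraint_graph(fam,
                        orthology = pairs(c("a", "b"), c("b", "c"), c("c", "d")),
                        unknown = pairs(c("a", "c")))
  pp <- preprocess_forced_edges(g)
  expect_false(pp$contradiction)
  expect_identical(unname(pp$forced[orthocons:::pair_key("a", "c")]), "E")
  expect_true(orthocons:::pair_key("a", "c") %in% pp$graph$E)
  # cross-check: the paralogy completion is indeed unsatisfiable
  expect_identical(build_ds_tree(realize(g, character()))$status, "unsatisfiable")

  # a bare P4 with no unknowns is a contradiction (unsatisfiable)
  p4 <- constraint_graph(fam,
                         orthology = pairs(c("a", "b"), c("b", "c"), c("c", "d")))
  expect_true(preprocess_forced_edges(p4)$contradiction)
  expect_identical(check_cons(p4)$status, "inconsistent")
})

test_that("preprocessing never changes the branch-and-bound verdict", {
  set.seed(56)
  for (rep in 1:40) {
    n <- sample(3:5, 1L)
    k <- sample(2:4, 1L)
    spmap <- sample.int(k, n, replace = TRUE)
    spmap <- match(spmap, unique(spmap))
    fam <- oc_family(n, spmap)
    mk <- oc_random_masks(n, spmap, max_u = 4L)
    g <- oc_graph(fam, mk["E"], mk["U"])
    a <- check_cons(g)$status
    b <- check_cons(g, preprocess = FALSE)$status
    expect_identical(a, b)
  }
})
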