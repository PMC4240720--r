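test_that("lca returns the deepest common ancestral node", {
  t <- nwk("((a,b),c);")
  expect_identical(tree_lca(t, "a")$leaf, "a")
  expect_setequal(tree_leaves(tree_lca(t, c("a", "b"))), c("a", "b"))
  expect_setequal(tree_leaves(tree_lca(t, c("a", "c"))), c("a", "b", "c"))
  expect_error(tree_lca(t, c("a", "q")), "unknown leaf")

  # caterpillar: lca of the two deepest leaves vs ancestor-path intersection
  cat_nwk <- "((((a,b),c),d),e);"
  t2 <- nwk(cat_nwk)
  expect_setequal(tree_leaves(tree_lca(t2, c("a", "b"))), c("a", "b"))
  expect_setequal(tree_leaves(tree_lca(t2, c("a", "d"))), c("a", "b", "c", "d"))
})

test_that("restriction prunes leaves, suppresses unary nodes and keeps labels", {
  t <- nwk("((a,b),(c,d));")
  expect_true(trees_isomorphic(restrict_tree(t, tree_leaves(t)), t))
  expect_true(trees_isomorphic(restrict_tree(t, c("a", "c")), nwk("(a,c);")))

  # triplet sets of a restriction equal the subset-filtered triplets
  set.seed(21)
  for (rep in 1:15) {
    tree <- oc_random_ds_tree(paste0("L", 1:8))
    keep <- sample(tree_leaves(tree), sample(3:6, 1L))
    sub <- restrict_tree(tree, keep)
    trip_sub <- tree_triplets(sub)
    trip_all <- tree_triplets(tree)
    in_keep <- apply(trip_all, 1L, function(r) all(r %in% keep))
    want <- trip_all[in_keep, , drop = FALSE]
    key <- function(m) sort(orthocons:::triplet_key(m[, "x"], m[, "y"], m[, "z"]))
    expect_identical(key(trip_sub), key(want))
  }
})

test_that("display requires a label-isomorphic restriction", {
  t <- nwk("((a,b),c);")
  expect_true(displays(t, t))
  expect_true(displays(t, triplet_tree("a", "b", "c")))
  expect_false(displays(t, triplet_tree("a", "c", "b")))
  star <- nwk("(a,b,c);")
  expect_false(displays(star, triplet_tree("a", "b", "c")))
})

test_that("triplet enumeration matches restriction over all 3-subsets", {
  expect_identical(nrow(tree_triplets(nwk("(a,b,c);"))), 0L)
  t <- nwk("((a,b),(c,d));")
  got <- tree_triplets(t)
  key <- sort(orthocons:::triplet_key(got[, "x"], got[, "y"], got[, "z"]))
  expect_identical(key, sort(c("a|b|c", "a|b|d", "c|d|a", "c|d|b")))

  set.seed(22)
  for (rep in 1:10) {
    n <- sample(4:8, 1L)
    tree <- oc_random_ds_tree(paste0("L", 1:n))
    got <- tree_triplets(tree)
    gkey <- sort(orthocons:::triplet_key(got[, "x"], got[, "y"], got[, "z"]))
    # oracle: restrict to each 3-subset, keep binary restrictions
    want <- character()
    for (ss in utils::combn(sort(tree_leaves(tree)), 3L, simplify = FALSE)) {
      r3 <- restrict_tree(tree, ss)
      if (length(r3$children) == 2L) {
        cherry <- Find(function(ch) is.null(ch$leaf), r3$children)
        if (!is.null(cherry)) {
          pr <- sort(tree_leaves(cherry))
          out <- setdiff(ss, pr)
          want <- c(want, orthocons:::triplet_key(pr[1L], pr[2L], out))
        }
      }
    }
    expect_identical(gkey, sort(want))
  }
})

test_that("gene relations follow the event at the lca", {
  expect_identical(gene_relation(nwk("(a,b)S;"), "a", "b"), "orthologous")
  expect_identical(gene_relation(nwk("(a,b)D;"), "a", "b"), "paralogous")
  expect_error(gene_relation(nwk("(a,b)S;"), "a", "a"), "distinct")

  # same-species pairs in a simulated history are always paralogous
  set.seed(23)
  inst <- simulate_instance(sim_config(n_species = 4, dup_prob = 0.4,
                                       loss_prob = 0.05, seed = 99))
  M <- orthology_matrix(inst$history)
  sp <- inst$family$species[rownames(M)]
  same <- outer(sp, sp, "==") & upper.tri(M)
  expect_false(any(M[same]))
})

test_that("speciation triplets are those rooted at speciation nodes across species", {
  fam <- gene_family(c("a1", "b1", "e1"), c("a", "b", "e"))
  alld <- nwk("((a1,b1)D,e1)D;")
  expect_identical(nrow(speciation_triplets(alld, fam)), 0L)
  g <- nwk("((a1,b1)D,e1)S;")
  got <- speciation_triplets(g, fam)
  expect_identical(orthocons:::triplet_key(got[, "x"], got[, "y"], got[, "z"]),
                   "a|b|e")
  # a same-species grouped pair is skipped
  fam2 <- gene_family(c("a1", "a2", "e1"), c("a", "a", "e"))
  g2 <- nwk("((a1,a2)D,e1)S;")
  expect_identical(nrow(speciation_triplets(g2, fam2)), 0L)
})

test_that("satisfaction checks edges as orthology and non-edges as paralogy", {
  fam <- fam_distinct(3)
  star_d <- nwk("(a,b,c)D;")
  expect_true(satisfies(star_d, constraint_graph(fam)))
  r <- constraint_graph(fam, orthology = pairs(c("a", "b")))
  expect_false(satisfies(nwk("((a,b)D,c)D;"), r))
  expect_true(satisfies(nwk("((a,b)S,c)D;"), r))
  # unknown pairs are unconstrained
  ru <- constraint_graph(fam, orthology = pairs(c("a", "b")),
                         unknown = pairs(c("b", "c")))
  expect_true(satisfies(nwk("((a,b)S,c)D;"), ru))
  expect_error(satisfies(nwk("(a,b)S;"), r), "leaf set")
})

test_that("the node-wise and triplet-display consistency tests agree", {
  fam <- gene_family(c("ga", "gd", "ge"), c("a", "d", "e"))
  s <- nwk("(a,(d,e));")
  # ad|e forced at the speciation root clashes with the de|a of S
  g_bad <- nwk("((ga,gd)D,ge)S;")
  expect_false(is_consistent(g_bad, fam, s))
  expect_false(is_consistent(g_bad, fam, s, method = "triplets"))
  allD <- nwk("((ga,gd)D,ge)D;")
  expect_true(is_consistent(allD, fam, s))

  set.seed(24)
  for (rep in 1:40) {
    n <- sample(4:10, 1L)
    genes <- paste0("g", seq_len(n))
    g <- oc_random_ds_tree(genes)
    spmap <- oc_valid_species_map(g)
    fam <- gene_family(genes, spmap)
    k <- length(unique(spmap))
    stree <- random_species_tree(k)
    expect_identical(is_consistent(g, fam, stree),
                     is_consistent(g, fam, stree, method = "triplets"))
  }
})

test_that("Newick and NHX serializations round-trip", {
  s <- nwk("((a,b),(c,(d,e)),f);")
  expect_true(trees_isomorphic(nwk(tree_to_newick(s)), s))
  g <- nwk("((x1,y1)S,(x2,'weird name')D)S;")
  txt_label <- tree_to_newick(g, events = "label")
  txt_nhx <- tree_to_newick(g, events = "nhx")
  expect_match(txt_nhx, "NHX:Ev=Spec", fixed = TRUE)
  expect_true(trees_isomorphic(nwk(txt_label), g))
  expect_true(trees_isomorphic(nwk(txt_nhx), g))
  # single-leaf degenerate tree
  expect_identical(nwk("onlyleaf;")$leaf, "onlyleaf")

  set.seed(25)
  for (rep in 1:10) {
    tree <- oc_random_ds_tree(paste0("t", 1:7))
    expect_true(trees_isomorphic(nwk(tree_to_newick(tree, "nhx")), tree))
  }
})
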