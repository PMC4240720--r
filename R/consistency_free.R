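# Consistency with an UNKNOWN species tree. For full graphs the mandatory
# species triplets are exactly those forced by induced paths x-z-y
# (orthology edges zx, zy and a paralogy non-edge xy): in any satisfying
# DS-tree the lca of x and y is a duplication below a speciation, so
# s(x)s(y)|s(z) must appear in any compatible species tree. A species tree
# displaying all of them exists iff the graph is consistent; an Aho-style
# recursive clustering (BUILD) finds one or reports failure. Partial graphs
# are completed by a branch-and-bound over the unknown pairs, pruned by the
# triplet test and by satisfiability, with a forced-edge preprocessing
# pass.

#' Species triplets forced by induced paths of length three
#'
#' Enumerates every gene triple x, z, y with orthology edges zx and zy, a
#' paralogy non-edge xy (not unknown), and s(x) != s(y), and emits the
#' species triplet s(x)s(y)|s(z). These triplets must be displayed by any
#' species tree with which the graph is consistent.
#'
#' @param graph a [constraint_graph()].
#' @return character matrix with columns `x`, `y`, `z` (species labels),
#'   duplicates collapsed.
#' @export
extract_p3 <- function(graph) {
  genes <- sort(graph$family$genes)
  n <- length(genes)
  if (n < 3L) return(triplet_unkey(character()))
  adjE <- adjacency_of(graph$E, genes)
  adjEU <- adjE | adjacency_of(graph$U, genes)
  species <- graph$family$species
  keys <- character()
  for (zi in seq_len(n)) {
    nb <- which(adjE[zi, ])
    if (length(nb) < 2L) next
    prs <- utils::combn(nb, 2L)
    open <- !adjEU[cbind(prs[1L, ], prs[2L, ])]      # xy a paralogy non-edge
    if (!any(open)) next
    sx <- unname(species[genes[prs[1L, open]]])
    sy <- unname(species[genes[prs[2L, open]]])
    keep <- sx != sy
    if (any(keep)) {
      sz <- unname(species[genes[zi]])
      keys <- c(keys, triplet_key(sx[keep], sy[keep], rep(sz, sum(keep))))
    }
  }
  triplet_unkey(sort(unique(keys)))
}

#' Build a species tree displaying a set of rooted triplets (BUILD)
#'
#' Aho-style recursive clustering: at each level an auxiliary graph links
#' the grouped pair of every triplet whose three labels survive; the
#' connected components become the children clusters, and the recursion
#' fails when two or more labels remain in a single component. Species not
#' mentioned by any triplet fall out as singleton components, so they
#' attach without constraint and multi-way unconstrained splits stay
#' non-binary (a least-resolved tree).
#'
#' @param triplets character matrix with columns `x`, `y`, `z` (as from
#'   [extract_p3()] or [speciation_triplets()]).
#' @param all_species character vector of the species label set for the
#'   output tree (a superset of the triplet labels).
#' @return a nested-list species tree displaying every triplet, or `NULL`
#'   when no species tree does.
#' @export
build_species_tree <- function(triplets, all_species) {
  all_species <- sort(unique(as.character(all_species)))
  if (length(all_species) == 0L) stop("all_species must be nonempty")
  if (nrow(triplets) > 0L) {
    labs <- unique(as.vector(triplets))
    if (!all(labs %in% all_species)) {
      stop("triplet labels outside all_species: ",
           paste(setdiff(labs, all_species), collapse = ", "))
    }
    # a triplet whose outgroup equals a grouped label cannot be displayed
    if (any(triplets[, "z"] == triplets[, "x"] |
            triplets[, "z"] == triplets[, "y"])) {
      return(NULL)
    }
  }
  rec <- function(labels, trip) {
    if (length(labels) == 1L) return(leaf_node(labels))
    keep <- trip[, "x"] %in% labels & trip[, "y"] %in% labels &
      trip[, "z"] %in% labels
    trip <- trip[keep, , drop = FALSE]
    idx <- stats::setNames(seq_along(labels), labels)
    M <- matrix(FALSE, length(labels), length(labels))
    if (nrow(trip) > 0L) {
      M[cbind(idx[trip[, "x"]], idx[trip[, "y"]])] <- TRUE
      M[cbind(idx[trip[, "y"]], idx[trip[, "x"]])] <- TRUE
    }
    comps <- adj_components(M)
    if (length(comps) == 1L) return(NULL)
    comps <- comps[order(vapply(comps, function(ix) min(labels[ix]), ""))]
    kids <- vector("list", length(comps))
    for (k in seq_along(comps)) {
      r <- rec(labels[comps[[k]]], trip)
      if (is.null(r)) return(NULL)
      kids[[k]] <- r
    }
    inner_node(kids)
  }
  out <- rec(all_species, triplets)
  if (is.null(out)) return(NULL)
  # audit: every triplet displayed
  sidx <- tree_index(out)
  for (i in seq_len(nrow(triplets))) {
    if (!sidx_displays_triplet(sidx, triplets[i, "x"], triplets[i, "y"],
                               triplets[i, "z"])) {
      stop("internal error: BUILD output fails the display audit")
    }
  }
  out
}

new_cons_result <- function(status, species_tree = NULL, realization = NULL,
                            witness = NULL, reason = NULL) {
  structure(list(status = status, species_tree = species_tree,
                 realization = realization, witness = witness,
                 reason = reason),
            class = "cons_result")
}

#' @export
print.cons_result <- function(x, ...) {
  cat("Status:", x$status, "\n")
  if (!is.null(x$species_tree)) {
    cat("Species tree:", tree_to_newick(x$species_tree, events = "none"), "\n")
  }
  if (!is.null(x$witness)) {
    cat("Witness DS-tree:", tree_to_newick(x$witness, events = "label"), "\n")
  }
  if (!is.null(x$reason)) cat("Reason:", x$reason, "\n")
  invisible(x)
}

# Package a successful (full realization, species tree) into a result with
# an audited witness.
finish_cons_result <- function(full, stree, original) {
  wit <- build_consistent_ds_tree(full, stree)
  if (wit$status != "consistent") {
    stop("internal error: witness construction failed on an accepted realization")
  }
  if (!satisfies(wit$witness, original)) {
    stop("internal error: witness fails the original constraints")
  }
  new_cons_result("consistent", species_tree = stree, realization = full,
                  witness = wit$witness)
}

#' Star witness for orthology-only constraint sets
#'
#' When the only paralogy constraints are the trivial same-species ones,
#' consistency always holds: group each species' genes under a duplication
#' star, join the stars under a single speciation root, and pair it with
#' the star species tree. The witness realizes every cross-species pair as
#' orthology.
#'
#' @param family a [gene_family()].
#' @return a `cons_result` with the star constructions; with a single
#'   species the duplication star stands alone, and a single gene gives a
#'   leaf witness.
#' @export
orthology_only_witness <- function(family) {
  sp <- sort(unique(unname(family$species)))
  per_species <- lapply(sp, function(s) {
    g <- sort(family$genes[unname(family$species[family$genes]) == s])
    if (length(g) == 1L) leaf_node(g) else {
      inner_node(lapply(g, leaf_node), "D")
    }
  })
  witness <- if (length(per_species) == 1L) per_species[[1L]] else {
    inner_node(per_species, "S")
  }
  stree <- if (length(sp) == 1L) leaf_node(sp) else {
    inner_node(lapply(sp, leaf_node))
  }
  cross <- Filter(function(k) {
    p <- pair_unkey(k)
    family$species[p[1L]] != family$species[p[2L]]
  }, all_pair_keys(family$genes))
  full <- structure(list(family = family, E = sort(unlist(cross) %||% character()),
                         U = character()),
                    class = "constraint_graph")
  if (!satisfies(witness, full) || !is_consistent(witness, family, stree)) {
    stop("internal error: orthology-only construction fails its audit")
  }
  new_cons_result("consistent", species_tree = stree, realization = full,
                  witness = witness)
}

#' Star witness for paralogy-only constraint sets
#'
#' With no orthology constraints, the all-duplication star over all genes
#' satisfies the empty realization and is consistent with the star species
#' tree, so consistency always holds.
#'
#' @param family a [gene_family()].
#' @param graph optional [constraint_graph()] to check the precondition
#'   `E` empty against.
#' @return a `cons_result` with the star constructions.
#' @export
paralogy_only_witness <- function(family, graph = NULL) {
  if (!is.null(graph) && length(graph$E) > 0L) {
    stop("paralogy_only_witness requires an empty orthology set")
  }
  g <- sort(family$genes)
  witness <- if (length(g) == 1L) leaf_node(g) else {
    inner_node(lapply(g, leaf_node), "D")
  }
  sp <- sort(unique(unname(family$species)))
  stree <- if (length(sp) == 1L) leaf_node(sp) else {
    inner_node(lapply(sp, leaf_node))
  }
  full <- structure(list(family = family, E = character(), U = character()),
                    class = "constraint_graph")
  if (!satisfies(witness, full) || !is_consistent(witness, family, stree)) {
    stop("internal error: paralogy-only construction fails its audit")
  }
  new_cons_result("consistent", species_tree = stree, realization = full,
                  witness = witness)
}

#' Consistency of a full constraint graph with an unknown species tree
#'
#' A satisfiable full constraint graph is consistent exactly when some
#' species tree displays all its forced triplets ([extract_p3()]); the
#' check therefore runs BUILD on that set and, on success, constructs and
#' audits a witness DS-tree against the returned species tree.
#'
#' @param graph a full [constraint_graph()] (U empty).
#' @return a `cons_result`.
#' @export
check_consistency_full <- function(graph) {
  if (!is_full_graph(graph)) {
    stop("check_consistency_full requires a full graph (U empty)")
  }
  graph <- normalize_constraints(graph)
  assert_valid(graph)
  if (build_ds_tree(graph)$status != "satisfiable") {
    return(new_cons_result("inconsistent", reason = "not satisfiable"))
  }
  stree <- build_species_tree(extract_p3(graph),
                              unique(unname(graph$family$species)))
  if (is.null(stree)) {
    return(new_cons_result("inconsistent", reason = "forced triplets are incompatible"))
  }
  finish_cons_result(graph, stree, graph)
}

#' Forced-edge preprocessing of a partial constraint graph
#'
#' Repeatedly applies two reduction rules until fixpoint: (a) an induced
#' path on four vertices of the orthology graph (or of the complement of
#' the full realization) whose four vertices span exactly one unknown pair
#' can only be destroyed by deciding that pair one way, so the decision is
#' forced — and a spanned P4 with no unknown pair at all proves
#' unsatisfiability; (b) a path x-z-y with both edges in E and xy unknown
#' is forced to orthology whenever deciding xy as paralogy would create a
#' species triplet contradicting one already in the forced set (or an
#' undisplayable triplet with a repeated species). A pair forced both ways
#' is a contradiction, which proves inconsistency.
#'
#' @param graph a valid [constraint_graph()].
#' @return list with `graph` (the reduced graph), `forced` (named character
#'   vector, pair key to `"E"` or `"P"`) and `contradiction` (logical; when
#'   `TRUE` the input graph is not consistent).
#' @export
preprocess_forced_edges <- function(graph) {
  graph <- normalize_constraints(graph)
  assert_valid(graph)
  forced <- character(0)
  repeat {
    want <- list()
    note <- function(key, how) want[[key]] <<- union(want[[key]], how)
    genes <- sort(graph$family$genes)
    n <- length(genes)
    adjE <- adjacency_of(graph$E, genes)
    adjU <- adjacency_of(graph$U, genes)
    adjC <- !(adjE | adjU)
    diag(adjC) <- FALSE

    # rule (a) on the orthology graph and on the complement of R(U)
    if (n >= 4L) {
      quads <- utils::combn(n, 4L)
      # pair order of upper.tri() on a 4x4, matching p4_pattern_table
      ut_i <- c(1L, 1L, 2L, 1L, 2L, 3L)
      ut_j <- c(2L, 3L, 3L, 4L, 4L, 4L)
      for (q in seq_len(ncol(quads))) {
        ix <- quads[, q]
        for (side in 1:2) {
          M <- if (side == 1L) adjE else adjC
          sub <- M[ix, ix]
          code <- sum(2^(0:5)[sub[upper.tri(sub)]])
          if (!p4_pattern_table[code + 1L]) next
          usub <- adjU[ix, ix]
          uin <- which(usub[upper.tri(usub)])
          if (length(uin) == 0L) {
            # permanent P4: no realization destroys it
            return(list(graph = graph, forced = forced, contradiction = TRUE))
          }
          if (length(uin) == 1L) {
            key <- pair_key(genes[ix[ut_i[uin]]], genes[ix[ut_j[uin]]])
            note(key, if (side == 1L) "E" else "P")
          }
        }
      }
    }

    # rule (b): E-paths x-z-y with xy unknown whose paralogy completion
    # creates a triplet clashing with the forced set
    if (length(graph$U) > 0L) {
      p3r <- extract_p3(graph)
      p3keys <- if (nrow(p3r) == 0L) character() else {
        triplet_key(p3r[, "x"], p3r[, "y"], p3r[, "z"])
      }
      species <- graph$family$species
      for (zi in seq_len(n)) {
        nb <- which(adjE[zi, ])
        if (length(nb) < 2L) next
        prs <- utils::combn(nb, 2L)
        for (p in seq_len(ncol(prs))) {
          xi <- prs[1L, p]; yi <- prs[2L, p]
          if (!adjU[xi, yi]) next
          sx <- unname(species[genes[xi]]); sy <- unname(species[genes[yi]])
          sz <- unname(species[genes[zi]])
          if (sx == sy) next
          key <- pair_key(genes[xi], genes[yi])
          if (sz == sx || sz == sy) {
            # paralogy would force an undisplayable triplet
            note(key, "E")
          } else {
            clash <- c(triplet_key(sx, sz, sy), triplet_key(sy, sz, sx))
            if (any(clash %in% p3keys)) note(key, "E")
          }
        }
      }
    }

    if (length(want) == 0L) break
    if (any(vapply(want, length, 0L) > 1L)) {
      return(list(graph = graph, forced = forced, contradiction = TRUE))
    }
    new_forced <- vapply(want, `[[`, "", 1L)
    clash <- intersect(names(new_forced), names(forced))
    if (any(forced[clash] != new_forced[clash])) {
      return(list(graph = graph, forced = forced, contradiction = TRUE))
    }
    forced <- c(forced, new_forced[setdiff(names(new_forced), names(forced))])
    toE <- names(new_forced)[new_forced == "E"]
    toP <- names(new_forced)[new_forced == "P"]
    graph$E <- sort(union(graph$E, toE))
    graph$U <- sort(setdiff(graph$U, c(toE, toP)))
    if (length(validate_constraints(graph)) > 0L) {
      # e.g. a same-species pair forced to orthology
      return(list(graph = graph, forced = forced, contradiction = TRUE))
    }
  }
  list(graph = graph, forced = forced, contradiction = FALSE)
}

#' Consistency of a partial constraint graph with an unknown species tree
#'
#' Exact branch-and-bound over the unknown pairs. At each search node the
#' forced triplets of the current partial graph are fed to BUILD (pruning
#' when they are incompatible) and satisfiability is rechecked with the
#' remaining unknowns treated as wildcards (pruning when even that fails).
#' When no unknowns remain the current full graph together with the BUILD
#' tree is a consistent solution. Branching decides one unknown pair, the
#' orthology branch first; pairs lying inside an induced P4 of the
#' orthology graph are branched on first, with lexicographic tie-breaking.
#' Worst-case exponential in the number of unknown pairs.
#'
#' @param graph a valid [constraint_graph()].
#' @param preprocess apply [preprocess_forced_edges()] first (default
#'   `TRUE`).
#' @param max_nodes safety cap on the number of search nodes; exceeding it
#'   raises an error of class `orthocons_search_limit`, never a wrong
#'   verdict.
#' @return a `cons_result`; on success `realization` is the chosen full
#'   constraint graph, `species_tree` displays all its forced triplets and
#'   `witness` is an audited DS-tree consistent with it.
#' @export
check_cons <- function(graph, preprocess = TRUE, max_nodes = Inf) {
  original <- normalize_constraints(graph)
  assert_valid(original)
  work <- original
  if (preprocess) {
    pp <- preprocess_forced_edges(original)
    if (pp$contradiction) {
      return(new_cons_result("inconsistent", reason = "forced-edge contradiction"))
    }
    work <- pp$graph
  }
  state <- new.env(parent = emptyenv())
  state$nodes <- 0L
  rec <- function(g) {
    state$nodes <- state$nodes + 1L
    if (state$nodes > max_nodes) {
      stop(structure(list(message = sprintf("search node cap exceeded (%d nodes)",
                                            state$nodes),
                          call = NULL),
                     class = c("orthocons_search_limit", "error", "condition")))
    }
    stree <- build_species_tree(extract_p3(g), unique(unname(g$family$species)))
    if (is.null(stree)) return(NULL)
    if (build_ds_tree(g)$status != "satisfiable") return(NULL)
    if (length(g$U) == 0L) return(list(full = g, stree = stree))
    e <- pick_branch_edge(g)
    g_orth <- g
    g_orth$E <- sort(union(g$E, e))
    g_orth$U <- setdiff(g$U, e)
    r <- rec(g_orth)
    if (!is.null(r)) return(r)
    g_par <- g
    g_par$U <- setdiff(g$U, e)
    rec(g_par)
  }
  res <- rec(work)
  if (is.null(res)) return(new_cons_result("inconsistent"))
  finish_cons_result(res$full, res$stree, original)
}

# Branch-edge heuristic: prefer an unknown pair whose endpoints both lie in
# an induced P4 of the orthology graph; lexicographically first otherwise.
pick_branch_edge <- function(g) {
  genes <- sort(g$family$genes)
  hit <- adj_find_p4(adjacency_of(g$E, genes))
  if (!is.null(hit)) {
    quad <- genes[hit]
    inquad <- g$U[apply(pair_unkey(g$U), 1L, function(p) all(p %in% quad))]
    if (length(inquad) > 0L) return(inquad[1L])
  }
  g$U[1L]
}
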