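# Consistency with a GIVEN species tree S. The satisfiability recursion is
# kept, but a speciation node is only allowed when the components of the
# complement of the full realization can be grouped into a speciation
# partition: parts whose species-lcas are pairwise unrelated in S. The
# canonical partition groups each component under the shallowest
# component-lca ancestral to it; it is the finest grouping forced by
# necessity, and no alternative partitions need to be enumerated.

# Assign components (given their species-lca node ids in sidx) to parts.
# Returns an integer part index per component, or NULL when the grouping
# collapses to a single part (no non-trivial speciation partition exists).
group_components_by_lca <- function(lca_ids, sidx) {
  k <- length(lca_ids)
  ord <- order(sidx$depth[lca_ids])   # shallowest first
  heads <- integer(0)                 # node ids heading each part
  part <- integer(k)
  for (i in ord) {
    nid <- lca_ids[i]
    assigned <- FALSE
    for (h in seq_along(heads)) {
      if (idx_is_anc(sidx, heads[h], nid)) {
        part[i] <- h
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      heads <- c(heads, nid)
      part[i] <- length(heads)
    }
  }
  if (max(part) < 2L) return(NULL)
  part
}

#' Group connected components into a speciation partition
#'
#' A speciation partition of a component set is a non-trivial partition
#' whose parts have pairwise unrelated species-lcas in the species tree; it
#' is exactly what licenses a speciation node above the components. Two
#' components must share a part whenever one component's species-lca lies
#' on the path from the other's to the root, so grouping each component
#' under the shallowest ancestral component-lca (a preorder sweep of S)
#' yields the canonical partition.
#'
#' @param components list of gene sets (character vectors).
#' @param family a [gene_family()] covering all component genes.
#' @param stree species tree containing every species involved.
#' @return list of parts (each a list of the input gene sets), parts and
#'   members ordered by smallest gene, or `NULL` when only the trivial
#'   single-part grouping exists.
#' @export
find_speciation_partition <- function(components, family, stree) {
  stopifnot(is.list(components), length(components) >= 1L)
  sidx <- tree_index(stree)
  lca_ids <- vapply(components, function(comp) {
    sp <- unique(species_of(family, comp))
    ids <- sidx$leaf_ids[sp]
    if (anyNA(ids)) {
      stop("species missing from the species tree: ",
           paste(sp[is.na(ids)], collapse = ", "))
    }
    idx_lca(sidx, unname(ids))
  }, 0L)
  part <- group_components_by_lca(lca_ids, sidx)
  if (is.null(part)) return(NULL)
  parts <- lapply(seq_len(max(part)), function(p) {
    members <- components[part == p]
    members[order(vapply(members, min, ""))]
  })
  parts[order(vapply(parts, function(p) min(p[[1L]]), ""))]
}

# Core recursion; genes/adjE/adjU as in sat_recurse, species = named map,
# sidx = indexed species tree. Returns list(ok, tree | failed).
cons_recurse <- function(genes, adjE, adjU, species, sidx) {
  n <- length(genes)
  if (n == 1L) return(list(ok = TRUE, tree = leaf_node(genes)))

  recurse_sets <- function(sets, ev) {
    # genes are sorted, so ordering by smallest index is lexicographic
    sets <- sets[order(vapply(sets, `[`, 0L, 1L))]
    kids <- vector("list", length(sets))
    for (k in seq_along(sets)) {
      ix <- sets[[k]]
      r <- cons_recurse(genes[ix], adjE[ix, ix, drop = FALSE],
                        adjU[ix, ix, drop = FALSE], species, sidx)
      if (!r$ok) return(r)
      kids[[k]] <- r$tree
    }
    list(ok = TRUE, tree = inner_node(kids, ev))
  }

  # Condition 1: empty realization disconnected, every component consistent.
  compsE <- adj_components(adjE)
  if (length(compsE) > 1L) {
    r <- recurse_sets(compsE, "D")
    if (r$ok) return(r)
    # fall through: the theorem is an OR of conditions, so the speciation
    # route is still attempted before declaring inconsistency
  }

  # Condition 2: complement of the full realization disconnected, its
  # components grouped by a speciation partition, every part consistent.
  adjC <- !(adjE | adjU)
  diag(adjC) <- FALSE
  compsC <- adj_components(adjC)
  if (length(compsC) > 1L) {
    lca_ids <- vapply(compsC, function(ix) {
      sp <- unique(unname(species[genes[ix]]))
      idx_lca(sidx, unname(sidx$leaf_ids[sp]))
    }, 0L)
    part <- group_components_by_lca(lca_ids, sidx)
    if (!is.null(part)) {
      part_sets <- lapply(seq_len(max(part)), function(p) {
        sort(unlist(compsC[part == p], use.names = FALSE))
      })
      r <- recurse_sets(part_sets, "S")
      if (r$ok) return(r)
    }
  }
  list(ok = FALSE, failed = genes)
}

#' Decide consistency with a given species tree and build a witness
#'
#' Modifies the satisfiability recursion of [build_ds_tree()] so that a
#' speciation node is created only above the parts of a speciation
#' partition (see [find_speciation_partition()]); duplication splits are
#' unchanged. The returned witness, when it exists, both satisfies the
#' constraint graph and is consistent with the species tree, and its
#' speciation nodes' children are the parts of the partitions found along
#' the way. Runs in cubic time.
#'
#' @param graph a valid [constraint_graph()].
#' @param stree species tree containing the species of every gene.
#' @return a `sat_result` with `status` `"consistent"` (plus `witness` and
#'   `chosen_realization`) or `"inconsistent"` (plus `failed_at`).
#' @export
build_consistent_ds_tree <- function(graph, stree) {
  graph <- normalize_constraints(graph)
  assert_valid(graph)
  sidx <- tree_index(stree)
  sp <- unique(unname(graph$family$species))
  missing <- setdiff(sp, names(sidx$leaf_ids))
  if (length(missing) > 0L) {
    stop("species missing from the species tree: ", paste(missing, collapse = ", "))
  }
  genes <- sort(graph$family$genes)
  r <- cons_recurse(genes, adjacency_of(graph$E, genes),
                    adjacency_of(graph$U, genes),
                    graph$family$species, sidx)
  if (!r$ok) {
    return(new_sat_result("inconsistent", failed_at = r$failed))
  }
  if (!satisfies(r$tree, graph) ||
      !is_consistent(r$tree, graph$family, stree)) {
    stop("internal error: witness fails the consistency audit")
  }
  new_sat_result("consistent", witness = r$tree,
                 chosen_realization = realization_from_witness(r$tree, graph))
}
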