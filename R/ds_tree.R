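# Orthology/paralogy semantics of DS-trees and the two consistency
# predicates: the node-wise definition (every speciation node separates
# species clades that are unrelated in S) and the equivalent triplet
# formulation (S displays every speciation triplet of the DS-tree).

#' Orthology relation induced by a DS-tree, as a logical matrix
#'
#' Two genes are orthologous w.r.t. a DS-tree when their least common
#' ancestor is a speciation node, paralogous when it is a duplication node.
#' One postorder pass fills the full gene-by-gene matrix.
#'
#' @param g a DS-tree (every internal node labeled `"S"` or `"D"`).
#' @return symmetric logical matrix over the leaves (TRUE = orthologous);
#'   the diagonal is `NA`.
#' @export
orthology_matrix <- function(g) {
  genes <- sort(tree_leaves(g))
  n <- length(genes)
  M <- matrix(NA, n, n, dimnames = list(genes, genes))
  pos <- stats::setNames(seq_len(n), genes)
  rec <- function(node) {
    if (is_leaf_node(node)) return(pos[[node$leaf]])
    if (is.null(node$event)) stop("DS-tree has an unlabeled internal node")
    sets <- lapply(node$children, rec)
    orth <- node$event == "S"
    k <- length(sets)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        M[sets[[i]], sets[[j]]] <<- orth
        M[sets[[j]], sets[[i]]] <<- orth
      }
    }
    unlist(sets, use.names = FALSE)
  }
  rec(g)
  M
}

#' Orthology or paralogy relation of two genes w.r.t. a DS-tree
#'
#' @param g a DS-tree.
#' @param x,y two distinct leaves of `g`.
#' @return `"orthologous"` if the lca of `x` and `y` is a speciation node,
#'   `"paralogous"` if it is a duplication node.
#' @export
gene_relation <- function(g, x, y) {
  if (identical(x, y)) stop("x and y must be distinct genes")
  idx <- tree_index(g)
  ids <- idx_leaf_id(idx, c(x, y))
  v <- idx_lca2(idx, ids[1L], ids[2L])
  ev <- idx$event[v]
  if (is.na(ev)) stop("lca is not an internal node")
  if (ev == "S") "orthologous" else "paralogous"
}

#' Speciation triplets of a DS-tree
#'
#' For every rooted triplet xy|z of the DS-tree whose root (the lca of the
#' three genes) is a speciation node and whose grouped genes belong to
#' different species, the species-level triplet s(x)s(y)|s(z) is emitted.
#' Duplicates are collapsed. Triplets whose outgroup species coincides with
#' a grouped species are emitted as-is; no species tree can display them,
#' and the supertree stage rejects them downstream.
#'
#' @param g a DS-tree.
#' @param family a [gene_family()] covering the leaves of `g`.
#' @return character matrix with columns `x`, `y`, `z` of species labels,
#'   one row per distinct speciation triplet s(x)s(y)|s(z), x < y.
#' @export
speciation_triplets <- function(g, family) {
  lv <- tree_leaves(g)
  if (!all(lv %in% family$genes)) {
    stop("DS-tree leaves must belong to the gene family")
  }
  keys <- character()
  rec <- function(node) {
    if (is_leaf_node(node)) return(node$leaf)
    sets <- lapply(node$children, rec)
    if (node$event == "S") {
      all_lv <- unlist(sets, use.names = FALSE)
      for (i in seq_along(sets)) {
        Li <- sets[[i]]
        if (length(Li) < 2L) next
        zz <- setdiff(all_lv, Li)
        if (length(zz) == 0L) next
        prs <- utils::combn(Li, 2L)
        sx <- rep(unname(family$species[prs[1L, ]]), each = length(zz))
        sy <- rep(unname(family$species[prs[2L, ]]), each = length(zz))
        sz <- rep(unname(family$species[zz]), times = ncol(prs))
        ok <- sx != sy
        if (any(ok)) {
          keys <<- c(keys, triplet_key(sx[ok], sy[ok], sz[ok]))
        }
      }
    }
    unlist(sets, use.names = FALSE)
  }
  rec(g)
  triplet_unkey(sort(unique(keys)))
}

#' Does a DS-tree satisfy a constraint graph?
#'
#' True when every orthology edge of the graph is orthologous w.r.t. the
#' tree and every paralogy non-edge is paralogous; unknown pairs are
#' unconstrained. For a full graph this is exactly the statement that the
#' orthology relation induced by the tree equals the edge set E.
#'
#' @param g a DS-tree whose leaf set equals the graph's genes.
#' @param graph a [constraint_graph()].
#' @export
satisfies <- function(g, graph) {
  lv <- tree_leaves(g)
  if (!setequal(lv, graph$family$genes)) {
    stop("the DS-tree leaf set must equal the graph's gene set")
  }
  M <- orthology_matrix(g)
  if (length(graph$E) > 0L) {
    em <- pair_unkey(graph$E)
    if (!all(M[em])) return(FALSE)
  }
  nonedges <- setdiff(all_pair_keys(graph$family$genes),
                      union(graph$E, graph$U))
  if (length(nonedges) > 0L) {
    pm <- pair_unkey(nonedges)
    if (any(M[pm])) return(FALSE)
  }
  TRUE
}

# Internal: node-wise consistency test on indexed structures.
consistent_by_definition <- function(gidx, species, sidx) {
  leafsets <- idx_leafsets(gidx)
  sp_leaf_id <- function(labels) {
    sp <- unique(unname(species[labels]))
    ids <- sidx$leaf_ids[sp]
    if (anyNA(ids)) {
      stop("species missing from the species tree: ",
           paste(sp[is.na(ids)], collapse = ", "))
    }
    unname(ids)
  }
  for (v in seq_len(gidx$n)) {
    if (is.na(gidx$event[v]) || gidx$event[v] != "S") next
    kids <- gidx$kids[[v]]
    lcas <- vapply(kids, function(k) idx_lca(sidx, sp_leaf_id(leafsets[[k]])), 0L)
    m <- length(lcas)
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (!idx_unrelated(sidx, lcas[i], lcas[j])) return(FALSE)
      }
    }
  }
  TRUE
}

# Internal: does the species tree (indexed) display species triplet xy|z?
sidx_displays_triplet <- function(sidx, x, y, z) {
  if (z == x || z == y) return(FALSE)
  ids <- sidx$leaf_ids[c(x, y, z)]
  if (anyNA(ids)) {
    stop("species missing from the species tree: ",
         paste(c(x, y, z)[is.na(ids)], collapse = ", "))
  }
  lxy <- idx_lca2(sidx, ids[[1L]], ids[[2L]])
  lxyz <- idx_lca2(sidx, lxy, ids[[3L]])
  sidx$depth[lxy] > sidx$depth[lxyz]
}

#' Consistency of a DS-tree with a species tree
#'
#' A DS-tree is consistent with a species tree S when, for every speciation
#' node and every two of its children, the S-lcas of the children's species
#' sets are unrelated in S (neither is an ancestor of the other). An
#' equivalent formulation is that S displays every speciation triplet of
#' the DS-tree; both routes are implemented and agree.
#'
#' @param g a DS-tree.
#' @param family a [gene_family()] covering the leaves of `g`.
#' @param stree a species tree containing every species of the family's
#'   genes present in `g`.
#' @param method `"definition"` (node-wise test, default) or `"triplets"`
#'   (speciation-triplet display test).
#' @export
is_consistent <- function(g, family, stree, method = c("definition", "triplets")) {
  method <- match.arg(method)
  lv <- tree_leaves(g)
  if (!all(lv %in% family$genes)) {
    stop("DS-tree leaves must belong to the gene family")
  }
  sidx <- tree_index(stree)
  sp <- unique(unname(family$species[lv]))
  missing <- setdiff(sp, names(sidx$leaf_ids))
  if (length(missing) > 0L) {
    stop("species missing from the species tree: ", paste(missing, collapse = ", "))
  }
  if (method == "definition") {
    consistent_by_definition(tree_index(g), family$species, sidx)
  } else {
    trs <- speciation_triplets(g, family)
    if (nrow(trs) == 0L) return(TRUE)
    all(vapply(seq_len(nrow(trs)), function(i) {
      sidx_displays_triplet(sidx, trs[i, "x"], trs[i, "y"], trs[i, "z"])
    }, logical(1L)))
  }
}
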