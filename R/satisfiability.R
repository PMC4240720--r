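# Satisfiability of a constraint graph: does some realization of the
# unknown pairs admit a DS-tree inducing exactly the known relations?
# Equivalently, is there a P4-free graph sandwiched between E and E + U?
# The recursive disconnection test builds a witness DS-tree as it goes:
# a disconnected empty realization licenses a duplication root over its
# components; a disconnected complement of the full realization licenses a
# speciation root; if neither splits, the graph is unsatisfiable.

# Core recursion on logical adjacency matrices; genes is the dimname
# vector. Returns list(ok, tree | failed).
sat_recurse <- function(genes, adjE, adjU) {
  n <- length(genes)
  if (n == 1L) return(list(ok = TRUE, tree = leaf_node(genes)))
  comps <- adj_components(adjE)
  if (length(comps) > 1L) {
    ev <- "D"
  } else {
    adjC <- !(adjE | adjU)
    diag(adjC) <- FALSE
    comps <- adj_components(adjC)
    if (length(comps) == 1L) {
      return(list(ok = FALSE, failed = genes))
    }
    ev <- "S"
  }
  # adj_components discovers components in order of smallest member index;
  # genes are sorted, so this is already the lexicographic order
  kids <- vector("list", length(comps))
  for (k in seq_along(comps)) {
    ix <- comps[[k]]
    r <- sat_recurse(genes[ix], adjE[ix, ix, drop = FALSE], adjU[ix, ix, drop = FALSE])
    if (!r$ok) return(r)
    kids[[k]] <- r$tree
  }
  list(ok = TRUE, tree = inner_node(kids, ev))
}

new_sat_result <- function(status, witness = NULL, chosen_realization = NULL,
                           failed_at = NULL) {
  structure(list(status = status, witness = witness,
                 chosen_realization = chosen_realization,
                 failed_at = failed_at),
            class = "sat_result")
}

#' @export
print.sat_result <- function(x, ...) {
  cat("Status:", x$status, "\n")
  if (!is.null(x$witness)) {
    cat("Witness DS-tree:", tree_to_newick(x$witness, events = "label"), "\n")
    if (length(x$chosen_realization) > 0L) {
      cat("Unknown pairs realized as orthology:",
          length(x$chosen_realization), "\n")
    }
  }
  if (!is.null(x$failed_at)) {
    cat("Failed on gene subset:", paste(x$failed_at, collapse = ", "), "\n")
  }
  invisible(x)
}

# U pairs that the witness realizes as orthology (makes the satisfaction
# auditable against the definition).
realization_from_witness <- function(witness, graph) {
  if (length(graph$U) == 0L) return(character())
  M <- orthology_matrix(witness)
  um <- pair_unkey(graph$U)
  graph$U[M[um]]
}

#' Decide satisfiability and build a witness DS-tree
#'
#' Recursively applies the disconnection test: if the empty realization is
#' disconnected, a duplication node joins the components; otherwise, if the
#' complement of the full realization is disconnected, a speciation node
#' joins the components; if neither holds on two or more genes, the graph
#' is unsatisfiable. When both splits apply, the duplication split is
#' preferred. The witness is a non-binary star-join built exactly as the
#' recursion prescribes. Runs in cubic time in the number of genes.
#'
#' @param graph a valid [constraint_graph()] (same-species unknown pairs
#'   are normalized to paralogy first).
#' @return a `sat_result` with `status` `"satisfiable"` (plus `witness` and
#'   `chosen_realization`, the unknown pairs orthologous in the witness) or
#'   `"unsatisfiable"` (plus `failed_at`, the gene subset on which the
#'   recursion halted).
#' @export
build_ds_tree <- function(graph) {
  graph <- normalize_constraints(graph)
  assert_valid(graph)
  genes <- sort(graph$family$genes)
  adjE <- adjacency_of(graph$E, genes)
  adjU <- adjacency_of(graph$U, genes)
  r <- sat_recurse(genes, adjE, adjU)
  if (!r$ok) {
    return(new_sat_result("unsatisfiable", failed_at = r$failed))
  }
  # satisfaction audit on the induced orthology relation (rows/cols of M
  # follow the same sorted gene order as adjE/adjU)
  M <- orthology_matrix(r$tree)
  off <- upper.tri(M)
  bad <- (adjE & !M) | (!adjE & !adjU & M)
  if (any(bad[off])) {
    stop("internal error: witness fails the satisfaction audit")
  }
  chosen <- if (length(graph$U) > 0L) graph$U[M[pair_unkey(graph$U)]] else character()
  new_sat_result("satisfiable", witness = r$tree, chosen_realization = chosen)
}

#' Satisfiability of a full constraint graph via P4-freeness
#'
#' A full constraint graph is satisfiable exactly when it is P4-free
#' (a cograph). This route is independent of the recursive construction in
#' [build_ds_tree()] and must agree with it.
#'
#' @param graph a full [constraint_graph()] (U empty).
#' @export
is_satisfiable_full <- function(graph) {
  if (!is_full_graph(graph)) stop("is_satisfiable_full requires a full graph (U empty)")
  is.null(find_induced_p4(graph))
}
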