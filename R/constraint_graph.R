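# Edge-bicoloured constraint graphs R = (V, E, U): vertices are genes,
# E holds known orthology pairs, U holds unknown pairs, and every pair in
# neither set is a known paralogy ("non-edge").

PAIR_SEP <- "\t"

#' Canonical key for an unordered gene pair
#'
#' Pairs are stored with the lexicographically smaller gene first so that
#' hashing, set operations and file output are deterministic.
#'
#' @param a,b character vectors of gene identifiers (recycled pairwise).
#' @return character vector of canonical pair keys.
#' @keywords internal
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = PAIR_SEP)
}

#' Split canonical pair keys back into a two-column matrix
#' @param keys character vector of keys produced by [pair_key()].
#' @return character matrix with one row per pair.
#' @keywords internal
pair_unkey <- function(keys) {
  if (length(keys) == 0L) {
    return(matrix(character(), 0L, 2L, dimnames = list(NULL, c("gene1", "gene2"))))
  }
  m <- matrix(unlist(strsplit(keys, PAIR_SEP, fixed = TRUE)),
              ncol = 2L, byrow = TRUE)
  colnames(m) <- c("gene1", "gene2")
  m
}

#' All unordered pairs over a gene set, as canonical keys
#' @param genes character vector of gene identifiers.
#' @keywords internal
all_pair_keys <- function(genes) {
  g <- sort(genes)
  if (length(g) < 2L) return(character())
  cb <- utils::combn(g, 2L)
  paste(cb[1L, ], cb[2L, ], sep = PAIR_SEP)
}

# Coerce user-supplied pair input (2-column matrix / data.frame, list of
# length-2 vectors, or canonical keys) into a sorted unique key vector.
as_pair_keys <- function(x, what = "pairs") {
  if (is.null(x) || length(x) == 0L) return(character())
  if (is.matrix(x) || is.data.frame(x)) {
    if (ncol(x) != 2L) stop(what, " must have exactly two columns")
    if (is.data.frame(x)) {
      keys <- pair_key(as.character(x[[1L]]), as.character(x[[2L]]))
    } else {
      keys <- pair_key(as.character(x[, 1L]), as.character(x[, 2L]))
    }
  } else if (is.list(x)) {
    bad <- vapply(x, function(p) length(p) != 2L, logical(1L))
    if (any(bad)) stop(what, " must be pairs of length 2")
    keys <- vapply(x, function(p) pair_key(as.character(p[[1L]]), as.character(p[[2L]])), "")
  } else if (is.character(x)) {
    if (!all(grepl(PAIR_SEP, x, fixed = TRUE))) {
      stop(what, " given as a character vector must be canonical pair keys")
    }
    keys <- x
  } else {
    stop("cannot interpret ", what)
  }
  sort(unique(keys))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gene family with its gene-to-species map
#'
#' A gene family is an ordered set of unique gene identifiers together with a
#' total map assigning each gene to exactly one species.
#'
#' @param genes character vector of unique gene identifiers.
#' @param species character vector of species identifiers, parallel to
#'   `genes` (or named by gene).
#' @return an object of class `gene_family` with elements `genes`
#'   (character) and `species` (named character, names are genes).
#' @examples
#' fam <- gene_family(c("x1", "y1"), c("spA", "spB"))
#' species_of(fam, "y1")
#' @export
gene_family <- function(genes, species) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("a gene family needs at least one gene")
  if (anyDuplicated(genes)) stop("gene identifiers must be unique")
  species <- if (!is.null(names(species))) {
    if (!all(genes %in% names(species))) stop("species map must cover every gene")
    as.character(species[genes])
  } else {
    if (length(species) != length(genes)) {
      stop("species must be named by gene or parallel to genes")
    }
    as.character(species)
  }
  if (anyNA(species) || any(species == "")) stop("every gene needs a species")
  structure(list(genes = genes, species = stats::setNames(species, genes)),
            class = "gene_family")
}

#' Look up the species of one or more genes
#' @param family a [gene_family()].
#' @param genes gene identifiers.
#' @return unnamed character vector of species identifiers.
#' @export
species_of <- function(family, genes) {
  sp <- family$species[genes]
  if (anyNA(sp)) stop("unknown gene(s): ", paste(genes[is.na(sp)], collapse = ", "))
  unname(sp)
}

#' @export
print.gene_family <- function(x, ...) {
  cat("Gene family:", length(x$genes), "genes over",
      length(unique(x$species)), "species\n")
  invisible(x)
}

#' Construct a constraint graph R = (V, E, U)
#'
#' Vertices are the genes of `family`; `orthology` lists known orthologous
#' pairs (the edge set E), `unknown` lists pairs whose relation is undecided
#' (U). Every pair appearing in neither set is a known paralogy. The
#' constructor canonicalizes and stores the sets as given; use
#' [validate_constraints()] to report invariant violations and
#' [normalize_constraints()] to resolve same-species unknowns to paralogy.
#'
#' @param family a [gene_family()].
#' @param orthology,unknown pair sets: a two-column matrix/data frame, a list
#'   of length-2 vectors, or canonical pair keys.
#' @return an object of class `constraint_graph` with elements `family`, `E`
#'   and `U` (sorted canonical pair keys). The graph is *full* when `U` is
#'   empty.
#' @examples
#' fam <- gene_family(c("a1", "b1", "c1"), c("A", "B", "C"))
#' r <- constraint_graph(fam, orthology = rbind(c("a1", "b1")),
#'                       unknown = rbind(c("b1", "c1")))
#' validate_constraints(r)
#' @export
constraint_graph <- function(family, orthology = NULL, unknown = NULL) {
  stopifnot(inherits(family, "gene_family"))
  structure(list(family = family,
                 E = as_pair_keys(orthology, "orthology"),
                 U = as_pair_keys(unknown, "unknown")),
            class = "constraint_graph")
}

#' Is a constraint graph full (no unknown pairs)?
#' @param graph a [constraint_graph()].
#' @export
is_full_graph <- function(graph) length(graph$U) == 0L

#' @export
print.constraint_graph <- function(x, ...) {
  n <- length(x$family$genes)
  npairs <- n * (n - 1L) / 2L
  cat("Constraint graph:", n, "genes,",
      length(x$E), "orthology edges,",
      length(x$U), "unknown edges,",
      npairs - length(x$E) - length(x$U), "paralogy non-edges\n")
  invisible(x)
}

#' Report invariant violations of a constraint graph
#'
#' Checks that E and U are disjoint, contain no self-pairs, have all
#' endpoints in the family, and that no same-species pair is constrained as
#' orthologous (two genes of one species can only be paralogs, since no
#' speciation separates them).
#'
#' @param graph a [constraint_graph()].
#' @return character vector of human-readable violations; empty when the
#'   graph is well-formed. Same-species pairs in U are reported as
#'   normalizable, not as hard violations (see [normalize_constraints()]).
#' @export
validate_constraints <- function(graph) {
  out <- character()
  fam <- graph$family
  both <- intersect(graph$E, graph$U)
  for (k in both) {
    p <- pair_unkey(k)
    out <- c(out, sprintf("pair {%s,%s} in both E and U", p[1L], p[2L]))
  }
  for (set in list(E = graph$E, U = graph$U)) {
    m <- pair_unkey(set)
    selfs <- m[, 1L] == m[, 2L]
    for (i in which(selfs)) {
      out <- c(out, sprintf("self-pair {%s,%s}", m[i, 1L], m[i, 2L]))
    }
    missing <- !(m[, 1L] %in% fam$genes) | !(m[, 2L] %in% fam$genes)
    for (i in which(missing & !selfs)) {
      out <- c(out, sprintf("pair {%s,%s} has endpoint outside the family",
                            m[i, 1L], m[i, 2L]))
    }
  }
  em <- pair_unkey(graph$E)
  if (nrow(em) > 0L) {
    known <- em[, 1L] %in% fam$genes & em[, 2L] %in% fam$genes & em[, 1L] != em[, 2L]
    same <- known & fam$species[em[, 1L]] == fam$species[em[, 2L]]
    for (i in which(same)) {
      out <- c(out, sprintf("same-species orthology {%s,%s}", em[i, 1L], em[i, 2L]))
    }
  }
  out
}

#' Resolve same-species unknown pairs to paralogy
#'
#' Two genes of the same species are necessarily paralogs, so a same-species
#' pair left unknown on input can be resolved immediately: it is removed
#' from U and becomes a paralogy non-edge.
#'
#' @param graph a [constraint_graph()].
#' @return the normalized graph.
#' @export
normalize_constraints <- function(graph) {
  if (length(graph$U) == 0L) return(graph)
  um <- pair_unkey(graph$U)
  fam <- graph$family
  ok1 <- um[, 1L] %in% fam$genes & um[, 2L] %in% fam$genes
  same <- ok1 & fam$species[um[, 1L]] == fam$species[um[, 2L]]
  graph$U <- graph$U[!same]
  graph
}

# Hard stop used by the decision algorithms, whose preconditions require a
# well-formed graph.
assert_valid <- function(graph) {
  v <- validate_constraints(graph)
  if (length(v) > 0L) {
    stop("invalid constraint graph: ", paste(v, collapse = "; "))
  }
  invisible(graph)
}

#' Realize a constraint graph by deciding a subset of its unknown pairs
#'
#' The realization R(F) chooses `F` as orthology edges and the remaining
#' unknown pairs as paralogy non-edges, yielding a full constraint graph.
#' `realize(graph, character())` is the empty realization and
#' `realize(graph, graph$U)` the full realization.
#'
#' @param graph a [constraint_graph()].
#' @param F subset of `graph$U`, in any pair format accepted by
#'   [constraint_graph()].
#' @return a full `constraint_graph` with edge set `E` \eqn{\cup} `F`.
#' @export
realize <- function(graph, F = character()) {
  keys <- as_pair_keys(F, "F")
  if (!all(keys %in% graph$U)) stop("F must be a subset of the unknown pairs U")
  graph$E <- sort(union(graph$E, keys))
  graph$U <- character()
  graph
}

#' Complement of a constraint graph
#'
#' Swaps the roles of orthology edges and paralogy non-edges while keeping
#' the unknown set fixed: the complement has edge set equal to all pairs in
#' neither E nor U. Complementation is an involution.
#'
#' @param graph a [constraint_graph()].
#' @export
graph_complement <- function(graph) {
  all_keys <- all_pair_keys(graph$family$genes)
  graph$E <- sort(setdiff(all_keys, union(graph$E, graph$U)))
  graph
}

#' Subgraph induced by a subset of genes
#'
#' Keeps exactly the E and U pairs with both endpoints in `X` and restricts
#' the family to `X` (preserving the original gene order).
#'
#' @param graph a [constraint_graph()].
#' @param X subset of the family's genes.
#' @export
induced_graph <- function(graph, X) {
  X <- as.character(X)
  if (!all(X %in% graph$family$genes)) {
    stop("X must be a subset of the family's genes")
  }
  genes <- graph$family$genes[graph$family$genes %in% X]
  fam <- gene_family(genes, graph$family$species[genes])
  keep <- function(keys) {
    if (length(keys) == 0L) return(keys)
    m <- pair_unkey(keys)
    keys[m[, 1L] %in% X & m[, 2L] %in% X]
  }
  structure(list(family = fam, E = keep(graph$E), U = keep(graph$U)),
            class = "constraint_graph")
}

# ---- adjacency helpers (internal) -----------------------------------------

# Logical adjacency matrix of a key set over `genes` (dimnames = genes).
adjacency_of <- function(keys, genes) {
  n <- length(genes)
  M <- matrix(FALSE, n, n, dimnames = list(genes, genes))
  if (length(keys) > 0L) {
    m <- pair_unkey(keys)
    M[cbind(m[, 1L], m[, 2L])] <- TRUE
    M[cbind(m[, 2L], m[, 1L])] <- TRUE
  }
  M
}

# Connected components of a logical adjacency matrix, as a list of integer
# index vectors (each sorted; list ordered by smallest member index).
adj_components <- function(M) {
  n <- nrow(M)
  seen <- logical(n)
  out <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    comp <- logical(n)
    comp[i] <- TRUE
    frontier <- i
    while (length(frontier) > 0L) {
      nb <- which(colSums(M[frontier, , drop = FALSE]) > 0L)
      frontier <- nb[!comp[nb]]
      comp[frontier] <- TRUE
    }
    seen <- seen | comp
    out[[length(out) + 1L]] <- which(comp)
  }
  out
}

#' Connected components of a full constraint graph
#'
#' Components are computed under the orthology edge set E (the empty
#' realization). Output is deterministic: components are sorted by their
#' lexicographically smallest member, and genes within a component are
#' sorted.
#'
#' @param graph a full [constraint_graph()] (U empty).
#' @return list of character vectors of genes.
#' @export
graph_components <- function(graph) {
  if (!is_full_graph(graph)) stop("graph_components requires a full graph (U empty)")
  genes <- graph$family$genes
  comps <- adj_components(adjacency_of(graph$E, genes))
  comps <- lapply(comps, function(ix) sort(genes[ix]))
  comps[order(vapply(comps, `[`, "", 1L))]
}

# 64-entry lookup: does a 6-bit edge pattern over 4 vertices induce a path
# on all four vertices? Bit order follows upper.tri() column-major order:
# (1,2),(1,3),(2,3),(1,4),(2,4),(3,4).
p4_pattern_table <- local({
  pairs4 <- rbind(c(1, 2), c(1, 3), c(2, 3), c(1, 4), c(2, 4), c(3, 4))
  vapply(0:63, function(code) {
    bits <- bitwAnd(bitwShiftR(code, 0:5), 1L) == 1L
    if (sum(bits) != 3L) return(FALSE)
    deg <- integer(4)
    for (b in which(bits)) {
      deg[pairs4[b, 1L]] <- deg[pairs4[b, 1L]] + 1L
      deg[pairs4[b, 2L]] <- deg[pairs4[b, 2L]] + 1L
    }
    # 3 edges, max degree 2 and no isolated vertex on 4 vertices <=> path
    max(deg) == 2L && min(deg) == 1L
  }, logical(1L))
})

# Internal: find an induced P4 in a logical adjacency matrix; returns an
# integer 4-vector (a,b,c,d) ordered along the path, or NULL.
adj_find_p4 <- function(M) {
  n <- nrow(M)
  if (n < 4L) return(NULL)
  # For every ordered adjacent pair (b,c): a adjacent to b but not c,
  # d adjacent to c but not b, a and d non-adjacent -> a-b-c-d induced.
  for (b in seq_len(n)) {
    for (cc in seq_len(n)) {
      if (cc == b || !M[b, cc]) next
      A <- which(M[b, ] & !M[cc, ])
      A <- A[A != cc]
      if (length(A) == 0L) next
      D <- which(M[cc, ] & !M[b, ])
      D <- D[D != b]
      if (length(D) == 0L) next
      sub <- !M[A, D, drop = FALSE]
      if (any(sub)) {
        hit <- which(sub, arr.ind = TRUE)[1L, ]
        return(c(A[hit[1L]], b, cc, D[hit[2L]]))
      }
    }
  }
  NULL
}

#' Find an induced path on four vertices (P4) in a full constraint graph
#'
#' A full constraint graph is satisfiable exactly when it is P4-free (a
#' cograph), so this is the elementary certificate of unsatisfiability.
#'
#' @param graph a full [constraint_graph()] (U empty).
#' @return a character vector `c(a, b, c, d)` such that exactly the pairs
#'   ab, bc, cd are orthology edges among the six pairs, or `NULL` when the
#'   graph is P4-free.
#' @export
find_induced_p4 <- function(graph) {
  if (!is_full_graph(graph)) stop("find_induced_p4 requires a full graph (U empty)")
  genes <- sort(graph$family$genes)
  hit <- adj_find_p4(adjacency_of(graph$E, genes))
  if (is.null(hit)) return(NULL)
  genes[hit]
}

#' Combine two full constraint graphs into a partial one
#'
#' Keeps only the relations on which the two graphs agree: the combined
#' orthology set is the intersection of the two edge sets, the combined
#' paralogy non-edges are the pairs that are non-edges in both, and every
#' pair on which the graphs disagree becomes unknown. This is how loose and
#' strict predictions from an orthology-detection run are merged into a
#' robust partial constraint set.
#'
#' @param r1,r2 full [constraint_graph()]s over the same gene family.
#' @return a (generally partial) `constraint_graph`.
#' @export
combine_graphs <- function(r1, r2) {
  if (!is_full_graph(r1) || !is_full_graph(r2)) {
    stop("combine_graphs is defined for full constraint graphs only")
  }
  if (!setequal(r1$family$genes, r2$family$genes) ||
      !identical(r1$family$species[sort(r1$family$genes)],
                 r2$family$species[sort(r2$family$genes)])) {
    stop("the two graphs must share the same gene family")
  }
  E <- intersect(r1$E, r2$E)
  U <- sort(setdiff(union(r1$E, r2$E), E))
  structure(list(family = r1$family, E = sort(E), U = U),
            class = "constraint_graph")
}
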