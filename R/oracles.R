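# Exhaustive reference implementations. These deliberately ignore every
# structural shortcut the main algorithms exploit: satisfiability is
# decided by enumerating all realizations and scanning all 4-subsets,
# consistency by enumerating all DS-trees and (for an unknown species
# tree) all rooted species trees. They are only usable at toy sizes and
# exist to validate the polynomial routes against first principles.

#' Enumerate all rooted leaf-labeled trees (multifurcations allowed)
#'
#' Recursive construction over set partitions: a tree on a leaf set is a
#' root whose children subtrees partition the leaves into at least two
#' blocks. Counts grow super-exponentially (1, 1, 4, 26, 236 for 1-5
#' leaves), so this is a small-n tool.
#'
#' @param labels character vector of leaf labels.
#' @return list of nested-list trees without event labels.
#' @export
all_rooted_trees <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 1L) return(list(leaf_node(labels)))
  out <- list()
  for (part in set_partitions(labels)) {
    if (length(part) < 2L) next
    per_block <- lapply(part, all_rooted_trees)
    for (combo in cross_index(lengths(per_block))) {
      kids <- mapply(function(trees, i) trees[[i]], per_block, combo,
                     SIMPLIFY = FALSE)
      out[[length(out) + 1L]] <- inner_node(kids)
    }
  }
  out
}

# All set partitions of a vector, each a list of blocks. Standard
# restricted-growth enumeration.
set_partitions <- function(items) {
  n <- length(items)
  if (n == 0L) return(list())
  if (n == 1L) return(list(list(items)))
  sub <- set_partitions(items[-n])
  out <- list()
  for (p in sub) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], items[n])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(items[n]))
  }
  out
}

# Cartesian product of index ranges, as a list of integer vectors.
cross_index <- function(sizes) {
  grid <- do.call(expand.grid, lapply(sizes, seq_len))
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}

# Count internal nodes of a nested-list tree.
count_internal <- function(tree) {
  if (is_leaf_node(tree)) return(0L)
  1L + sum(vapply(tree$children, count_internal, 0L))
}

# Apply an event labeling (vector over internal nodes, preorder) to a
# shape.
label_shape <- function(tree, events, pos = 1L) {
  if (is_leaf_node(tree)) return(list(tree = tree, pos = pos))
  ev <- events[pos]
  pos <- pos + 1L
  kids <- vector("list", length(tree$children))
  for (i in seq_along(tree$children)) {
    r <- label_shape(tree$children[[i]], events, pos)
    kids[[i]] <- r$tree
    pos <- r$pos
  }
  list(tree = inner_node(kids, ev), pos = pos)
}

#' Enumerate all DS-trees on a set of genes
#'
#' Every rooted multifurcating shape combined with every assignment of
#' duplication/speciation labels to its internal nodes.
#'
#' @param genes character vector of gene labels.
#' @return list of DS-trees.
#' @export
all_ds_trees <- function(genes) {
  shapes <- all_rooted_trees(genes)
  out <- list()
  for (sh in shapes) {
    k <- count_internal(sh)
    if (k == 0L) {
      out[[length(out) + 1L]] <- sh
      next
    }
    for (mask in 0:(2^k - 1L)) {
      ev <- ifelse(bitwAnd(bitwShiftR(mask, seq_len(k) - 1L), 1L) == 1L, "S", "D")
      out[[length(out) + 1L]] <- label_shape(sh, ev)$tree
    }
  }
  out
}

#' P4-freeness of a full constraint graph by exhaustive 4-subset scan
#'
#' @param graph a full [constraint_graph()] (U empty).
#' @export
brute_p4_free <- function(graph) {
  if (!is_full_graph(graph)) stop("brute_p4_free requires a full graph (U empty)")
  genes <- sort(graph$family$genes)
  n <- length(genes)
  if (n < 4L) return(TRUE)
  M <- adjacency_of(graph$E, genes)
  quads <- utils::combn(n, 4L)
  for (q in seq_len(ncol(quads))) {
    sub <- M[quads[, q], quads[, q]]
    code <- sum(2^(0:5)[sub[upper.tri(sub)]])
    if (p4_pattern_table[code + 1L]) return(FALSE)
  }
  TRUE
}

# All subsets of a key vector (list of character vectors).
all_subsets <- function(keys) {
  out <- list(character())
  for (k in keys) {
    out <- c(out, lapply(out, function(s) c(s, k)))
  }
  out
}

#' Satisfiability by brute force over all realizations
#'
#' Enumerates every subset F of the unknown pairs and checks the
#' realization R(F) for P4-freeness by exhaustive scan. Exponential in
#' |U|.
#'
#' @param graph a [constraint_graph()].
#' @export
brute_satisfiable <- function(graph) {
  graph <- normalize_constraints(graph)
  for (F in all_subsets(graph$U)) {
    if (brute_p4_free(realize(graph, F))) return(TRUE)
  }
  FALSE
}

#' Consistency with a given species tree by exhaustive DS-tree search
#'
#' Enumerates every realization and every DS-tree on the gene set, testing
#' satisfaction and the node-wise consistency definition directly. Only
#' usable for a handful of genes.
#'
#' @param graph a [constraint_graph()].
#' @param stree a species tree.
#' @export
brute_consistent_with <- function(graph, stree) {
  graph <- normalize_constraints(graph)
  trees <- all_ds_trees(sort(graph$family$genes))
  for (F in all_subsets(graph$U)) {
    full <- realize(graph, F)
    for (g in trees) {
      if (satisfies(g, full) && is_consistent(g, graph$family, stree)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Consistency with some species tree by exhaustive double enumeration
#'
#' Enumerates every rooted species tree on the family's species set and
#' delegates to [brute_consistent_with()].
#'
#' @param graph a [constraint_graph()].
#' @export
brute_consistent <- function(graph) {
  graph <- normalize_constraints(graph)
  sp <- sort(unique(unname(graph$family$species)))
  for (stree in all_rooted_trees(sp)) {
    if (brute_consistent_with(graph, stree)) return(TRUE)
  }
  FALSE
}
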