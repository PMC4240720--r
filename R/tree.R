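# Rooted trees as nested lists. A leaf is list(leaf = "label"); an internal
# node is list(children = list(...), event = "S"/"D"/NULL). Species trees
# carry no events; DS-trees label every internal node "S" (speciation) or
# "D" (duplication). Internal nodes may have any out-degree >= 2.

#' Leaf node constructor
#' @param label leaf label (gene or species identifier).
#' @export
leaf_node <- function(label) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  list(leaf = label)
}

#' Internal node constructor
#' @param children list of child nodes (length >= 2, or 1 only transiently).
#' @param event `"S"`, `"D"` or `NULL` (unlabeled, e.g. species trees).
#' @export
inner_node <- function(children, event = NULL) {
  stopifnot(is.list(children), length(children) >= 1L)
  if (!is.null(event)) stopifnot(event %in% c("S", "D"))
  list(children = children, event = event)
}

is_leaf_node <- function(node) !is.null(node$leaf)

#' Leaf labels of a tree, in left-to-right order
#' @param tree a nested-list tree.
#' @return character vector of leaf labels.
#' @export
tree_leaves <- function(tree) {
  if (is_leaf_node(tree)) return(tree$leaf)
  unlist(lapply(tree$children, tree_leaves), use.names = FALSE)
}

# ---- indexed form ---------------------------------------------------------

# Flatten a tree into parallel vectors (preorder): parent, depth, event,
# label, children ids, and a named leaf-id lookup. Used by every lca-heavy
# operation.
tree_index <- function(tree) {
  e <- new.env(parent = emptyenv())
  e$parent <- integer(0); e$depth <- integer(0)
  e$event <- character(0); e$label <- character(0)
  e$kids <- list()
  walk <- function(node, par, d) {
    i <- length(e$parent) + 1L
    e$parent[i] <- par
    e$depth[i] <- d
    e$event[i] <- if (is.null(node$event)) NA_character_ else node$event
    e$label[i] <- if (is_leaf_node(node)) node$leaf else NA_character_
    e$kids[[i]] <- integer(0)
    if (par > 0L) e$kids[[par]] <- c(e$kids[[par]], i)
    if (!is_leaf_node(node)) {
      for (ch in node$children) walk(ch, i, d + 1L)
    }
    i
  }
  walk(tree, 0L, 0L)
  leaf_ids <- which(!is.na(e$label))
  if (anyDuplicated(e$label[leaf_ids])) stop("leaf labels must be unique")
  list(parent = e$parent, depth = e$depth, event = e$event, label = e$label,
       kids = e$kids, n = length(e$parent),
       leaf_ids = stats::setNames(leaf_ids, e$label[leaf_ids]))
}

idx_lca2 <- function(idx, i, j) {
  while (idx$depth[i] > idx$depth[j]) i <- idx$parent[i]
  while (idx$depth[j] > idx$depth[i]) j <- idx$parent[j]
  while (i != j) {
    i <- idx$parent[i]
    j <- idx$parent[j]
  }
  i
}

idx_lca <- function(idx, ids) Reduce(function(a, b) idx_lca2(idx, a, b), ids)

# Is a an ancestor of b, or equal to it?
idx_is_anc <- function(idx, a, b) {
  while (idx$depth[b] > idx$depth[a]) b <- idx$parent[b]
  a == b
}

# Two nodes are unrelated when they differ and neither is an ancestor of
# the other.
idx_unrelated <- function(idx, a, b) {
  a != b && !idx_is_anc(idx, a, b) && !idx_is_anc(idx, b, a)
}

idx_leaf_id <- function(idx, labels) {
  ids <- idx$leaf_ids[labels]
  if (anyNA(ids)) {
    stop("unknown leaf label(s): ", paste(labels[is.na(ids)], collapse = ", "))
  }
  unname(ids)
}

# Leaf-label sets per node id (list of character vectors), one postorder pass.
idx_leafsets <- function(idx) {
  sets <- vector("list", idx$n)
  for (i in rev(seq_len(idx$n))) {
    sets[[i]] <- if (is.na(idx$label[i])) {
      unlist(sets[idx$kids[[i]]], use.names = FALSE)
    } else {
      idx$label[i]
    }
  }
  sets
}

#' Least common ancestor of a set of leaves
#'
#' @param tree a nested-list tree.
#' @param leaves nonempty character vector of leaf labels present in `tree`.
#' @return the subtree (nested list) rooted at the deepest node ancestral to
#'   all given leaves.
#' @export
tree_lca <- function(tree, leaves) {
  leaves <- unique(as.character(leaves))
  if (length(leaves) == 0L) stop("leaves must be nonempty")
  lv <- tree_leaves(tree)
  if (!all(leaves %in% lv)) {
    stop("unknown leaf label(s): ", paste(setdiff(leaves, lv), collapse = ", "))
  }
  rec <- function(node) {
    if (is_leaf_node(node)) {
      return(if (identical(node$leaf, leaves)) node else NULL)
    }
    if (!all(leaves %in% tree_leaves(node))) return(NULL)
    for (ch in node$children) {
      r <- rec(ch)
      if (!is.null(r)) return(r)
    }
    node
  }
  out <- rec(tree)
  if (is.null(out)) {
    # all leaves under one leaf is impossible unless a single leaf was asked
    out <- tree
  }
  out
}

#' Restrict a tree to a subset of its leaves
#'
#' The restriction is rooted at the least common ancestor of the kept
#' leaves; leaves outside the subset are removed and internal nodes left
#' with a single child are suppressed (the root is kept as the lca even
#' when that makes it the only survivor). Event labels are inherited by the
#' surviving nodes.
#'
#' @param tree a nested-list tree.
#' @param leaves nonempty subset of `tree_leaves(tree)`.
#' @return the restricted tree.
#' @export
restrict_tree <- function(tree, leaves) {
  leaves <- unique(as.character(leaves))
  if (length(leaves) == 0L) stop("leaves must be nonempty")
  all_lv <- tree_leaves(tree)
  if (!all(leaves %in% all_lv)) {
    stop("unknown leaf label(s): ", paste(setdiff(leaves, all_lv), collapse = ", "))
  }
  rec <- function(node) {
    if (is_leaf_node(node)) {
      return(if (node$leaf %in% leaves) node else NULL)
    }
    kids <- Filter(Negate(is.null), lapply(node$children, rec))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1L]])
    inner_node(kids, node$event)
  }
  rec(tree)
}

# Canonical form string: children sorted recursively, so two trees are
# label-isomorphic iff their canonical strings match.
tree_canonical <- function(tree, use_events = TRUE) {
  if (is_leaf_node(tree)) return(paste0("<", tree$leaf, ">"))
  ks <- sort(vapply(tree$children, tree_canonical, "", use_events = use_events))
  ev <- if (use_events && !is.null(tree$event)) tree$event else ""
  paste0("(", paste(ks, collapse = ","), ")", ev)
}

#' Label-isomorphism of two trees (child order ignored)
#'
#' @param a,b nested-list trees.
#' @param use_events compare internal event labels as well (default `TRUE`;
#'   set `FALSE` for plain topology comparison).
#' @export
trees_isomorphic <- function(a, b, use_events = TRUE) {
  tree_canonical(a, use_events) == tree_canonical(b, use_events)
}

#' Does one tree display another?
#'
#' `big` displays `small` when restricting `big` to the leaves of `small`
#' gives a tree label-isomorphic to `small`. Event labels are not compared:
#' display is a statement about topology. Note that a star restriction does
#' not display a binary triplet.
#'
#' @param big,small nested-list trees with `tree_leaves(small)` a subset of
#'   `tree_leaves(big)`.
#' @export
displays <- function(big, small) {
  lv <- tree_leaves(small)
  if (!all(lv %in% tree_leaves(big))) {
    stop("leaves of `small` must occur in `big`")
  }
  trees_isomorphic(restrict_tree(big, lv), small, use_events = FALSE)
}

#' Rooted triplet constructor xy|z
#'
#' @param x,y the grouped pair (unordered, must differ); `z` the outgroup.
#' @return a nested-list binary triplet tree.
#' @export
triplet_tree <- function(x, y, z) {
  stopifnot(x != y)
  inner_node(list(inner_node(list(leaf_node(min(x, y)), leaf_node(max(x, y)))),
                  leaf_node(z)))
}

# Canonical triplet keys "x|y|z" with x < y; used for set comparisons.
triplet_key <- function(x, y, z) {
  paste(pmin(x, y), pmax(x, y), z, sep = "|")
}

triplet_unkey <- function(keys) {
  if (length(keys) == 0L) {
    return(matrix(character(), 0L, 3L, dimnames = list(NULL, c("x", "y", "z"))))
  }
  m <- matrix(unlist(strsplit(keys, "|", fixed = TRUE)), ncol = 3L, byrow = TRUE)
  colnames(m) <- c("x", "y", "z")
  m
}

#' All rooted triplets of a tree
#'
#' Enumerates every 3-subset of leaves whose restriction is binary, with its
#' topology. For a binary tree on n leaves there are choose(n, 3) of them; a
#' star tree has none.
#'
#' @param tree a nested-list tree.
#' @return character matrix with columns `x`, `y`, `z`, one row per triplet
#'   xy|z (x < y lexicographically).
#' @export
tree_triplets <- function(tree) {
  xs <- character(); ys <- character(); zs <- character()
  rec <- function(node) {
    if (is_leaf_node(node)) return(node$leaf)
    sets <- lapply(node$children, rec)
    all_lv <- unlist(sets, use.names = FALSE)
    for (i in seq_along(sets)) {
      Li <- sets[[i]]
      if (length(Li) < 2L) next
      zz <- setdiff(all_lv, Li)
      if (length(zz) == 0L) next
      prs <- utils::combn(sort(Li), 2L)
      k <- ncol(prs)
      xs <<- c(xs, rep(prs[1L, ], each = length(zz)))
      ys <<- c(ys, rep(prs[2L, ], each = length(zz)))
      zs <<- c(zs, rep(zz, times = k))
    }
    all_lv
  }
  rec(tree)
  out <- cbind(x = xs, y = ys, z = zs)
  rownames(out) <- NULL
  out
}

# ---- Newick / NHX I-O -----------------------------------------------------

quote_nwk_label <- function(x) {
  bad <- grepl("[ \t()\\[\\]:;,']", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

#' Serialize a tree to a Newick string
#'
#' @param tree a nested-list tree.
#' @param events how to encode internal Dup/Spec labels: `"none"` drops
#'   them (species trees), `"label"` writes plain internal labels `S`/`D`,
#'   `"nhx"` writes `[&&NHX:Ev=Spec]`/`[&&NHX:Ev=Dup]` tags.
#' @return a single Newick string terminated by `;`.
#' @export
tree_to_newick <- function(tree, events = c("none", "label", "nhx")) {
  events <- match.arg(events)
  rec <- function(node) {
    if (is_leaf_node(node)) return(quote_nwk_label(node$leaf))
    body <- paste(vapply(node$children, rec, ""), collapse = ",")
    suffix <- ""
    if (!is.null(node$event)) {
      if (events == "label") suffix <- node$event
      if (events == "nhx") {
        suffix <- sprintf("[&&NHX:Ev=%s]", if (node$event == "S") "Spec" else "Dup")
      }
    }
    paste0("(", body, ")", suffix)
  }
  paste0(rec(tree), ";")
}

# ape::read.tree does the parsing; NHX event tags are rewritten to plain
# internal labels first, and the single-leaf degenerate case is handled
# directly (ape requires at least one internal node).
newick_to_tree <- function(text, events = c("auto", "none")) {
  events <- match.arg(events)
  text <- trimws(text)
  text <- gsub("\\)([^,();\\[\\]]*)\\[&&NHX:Ev=Spec\\]", ")S", text, perl = TRUE)
  text <- gsub("\\)([^,();\\[\\]]*)\\[&&NHX:Ev=Dup\\]", ")D", text, perl = TRUE)
  if (!grepl("(", text, fixed = TRUE)) {
    lab <- sub(";\\s*$", "", text)
    lab <- gsub("^'|'$", "", lab)
    if (!nzchar(lab)) stop("empty Newick string")
    return(leaf_node(lab))
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(phy)) stop("Newick parse error in: ", text)
  phylo_to_tree(phy, keep_events = events == "auto")
}

phylo_to_tree <- function(phy, keep_events = TRUE) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  kids <- vector("list", ntip + nnode)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], phy$edge[i, 2L])
  }
  ev_of <- function(id) {
    if (!keep_events || is.null(phy$node.label)) return(NULL)
    lab <- phy$node.label[id - ntip]
    if (is.na(lab) || !nzchar(lab)) return(NULL)
    switch(lab, S = "S", Spec = "S", D = "D", Dup = "D", NULL)
  }
  build <- function(id) {
    if (id <= ntip) return(leaf_node(phy$tip.label[id]))
    inner_node(lapply(kids[[id]], build), ev_of(id))
  }
  build(ntip + 1L)
}

#' Read a species tree from a Newick file
#'
#' Accepts non-binary trees and quoted labels; internal node labels are
#' ignored.
#'
#' @param path file path (or a connection readable by [readLines()]).
#' @return a nested-list tree without event labels.
#' @export
read_species_tree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  newick_to_tree(txt, events = "none")
}

#' Write a species tree to a Newick file
#' @param tree a nested-list tree.
#' @param path output file path.
#' @export
write_species_tree <- function(tree, path) {
  writeLines(tree_to_newick(tree, events = "none"), path)
}

#' Read a DS-tree (event-labeled gene tree)
#'
#' Accepts plain internal labels `S`/`D` as well as the NHX dialect with
#' `[&&NHX:Ev=Spec]` / `[&&NHX:Ev=Dup]` tags. Every internal node must carry
#' an event.
#'
#' @param path file path.
#' @return a nested-list DS-tree.
#' @export
read_ds_tree <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  tree <- newick_to_tree(txt, events = "auto")
  check <- function(node) {
    if (is_leaf_node(node)) return(invisible(NULL))
    if (is.null(node$event)) {
      stop("DS-tree has an internal node without a Dup/Spec label")
    }
    for (ch in node$children) check(ch)
  }
  check(tree)
  tree
}

#' Write a DS-tree to a file
#' @param tree a nested-list DS-tree.
#' @param path output file path.
#' @param format `"label"` for plain `S`/`D` internal labels (default) or
#'   `"nhx"` for NHX event tags.
#' @export
write_ds_tree <- function(tree, path, format = c("label", "nhx")) {
  format <- match.arg(format)
  writeLines(tree_to_newick(tree, events = format), path)
}
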