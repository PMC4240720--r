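# Shared machinery for the exhaustive reference checks: bitmask encodings
# of small graphs, a P4-freeness table over all full graphs on n vertices,
# and cached DS-tree profiles used to decide consistency questions by
# enumeration. Everything here is independent of the package's decision
# algorithms: satisfiability comes down to table lookups over 4-subsets,
# consistency to enumerating all DS-trees and species trees.

.oc_cache <- new.env(parent = emptyenv())

oc_memo <- function(key, expr) {
  if (!is.null(.oc_cache[[key]])) return(.oc_cache[[key]])
  val <- force(expr)
  .oc_cache[[key]] <- val
  val
}

# Pair index matrix over n sorted vertices, combn order: one row per pair.
oc_pairs <- function(n) t(utils::combn(n, 2L))

oc_mask_bits <- function(mask, m) {
  which(bitwAnd(bitwShiftR(mask, 0:(m - 1L)), 1L) == 1L)
}

oc_bits_mask <- function(bits) {
  if (length(bits) == 0L) return(0L)
  as.integer(sum(2^(bits - 1L)))
}

# All submasks of an integer mask (including 0 and mask itself).
oc_submasks <- function(mask) {
  subs <- integer(0)
  s <- mask
  repeat {
    subs <- c(subs, s)
    if (s == 0L) break
    s <- bitwAnd(s - 1L, mask)
  }
  subs
}

# Is a 6-bit code over the quad pairs (combn order 12,13,14,23,24,34) an
# induced path on all four vertices?
oc_is_p4_code <- local({
  quad_pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  vapply(0:63, function(code) {
    bits <- bitwAnd(bitwShiftR(code, 0:5), 1L) == 1L
    if (sum(bits) != 3L) return(FALSE)
    deg <- integer(4L)
    for (b in which(bits)) {
      deg[quad_pairs[b, ]] <- deg[quad_pairs[b, ]] + 1L
    }
    max(deg) == 2L && min(deg) == 1L
  }, logical(1L))
})

# P4-freeness of every full graph on n vertices, as a logical vector
# indexed by edge mask + 1 (combn pair order).
oc_p4free_table <- function(n) {
  oc_memo(paste0("p4free", n), {
    m <- choose(n, 2L)
    if (n < 4L) {
      rep(TRUE, 2^m)
    } else {
      pm <- oc_pairs(n)
      pair_pos <- matrix(0L, n, n)
      pair_pos[pm] <- seq_len(m)
      pair_pos[pm[, 2:1]] <- seq_len(m)
      quads <- utils::combn(n, 4L)
      out <- rep(TRUE, 2^m)
      masks <- 0:(2^m - 1L)
      for (q in seq_len(ncol(quads))) {
        vs <- quads[, q]
        qp <- utils::combn(vs, 2L)
        bitpos <- pair_pos[cbind(qp[1L, ], qp[2L, ])]
        code <- integer(length(masks))
        for (b in seq_len(6L)) {
          code <- code + bitwAnd(bitwShiftR(masks, bitpos[b] - 1L), 1L) * 2^(b - 1L)
        }
        out[oc_is_p4_code[code + 1L]] <- FALSE
      }
      out
    }
  })
}

# Brute-force satisfiability of an (Emask, Umask) bicolouring: is some
# realization P4-free?
oc_brute_sat <- function(Emask, Umask, p4tab) {
  any(p4tab[bitwOr(Emask, oc_submasks(Umask)) + 1L])
}

# Build a constraint graph from masks over the pair rows of oc_pairs(n).
oc_graph <- function(fam, Emask, Umask) {
  genes <- sort(fam$genes)
  pm <- oc_pairs(length(genes))
  gm <- cbind(genes[pm[, 1L]], genes[pm[, 2L]])
  m <- nrow(pm)
  constraint_graph(fam,
                   orthology = gm[oc_mask_bits(Emask, m), , drop = FALSE],
                   unknown = gm[oc_mask_bits(Umask, m), , drop = FALSE])
}

# ---- DS-tree profiles and enumeration-based consistency -------------------

# All set partitions of 1..n (list of lists of integer vectors).
oc_set_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (p in oc_set_partitions(n - 1L)) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# Profiles of every DS-tree on genes g1..gn: the orthology relation as a
# pair bitmask (combn order) and, per speciation node, the list of
# children leaf-index sets (what the node-wise consistency test needs).
oc_ds_profiles <- function(n) {
  oc_memo(paste0("prof", n), {
    genes <- paste0("g", seq_len(n))
    pm <- oc_pairs(n)
    pos <- stats::setNames(seq_len(n), genes)
    lapply(all_ds_trees(genes), function(tree) {
      M <- orthology_matrix(tree)
      vec <- M[cbind(genes[pm[, 1L]], genes[pm[, 2L]])]
      spec <- list()
      rec <- function(node) {
        if (!is.null(node$leaf)) return(pos[[node$leaf]])
        sets <- lapply(node$children, rec)
        if (identical(node$event, "S")) spec[[length(spec) + 1L]] <<- sets
        sort(unlist(sets, use.names = FALSE))
      }
      rec(tree)
      list(mask = oc_bits_mask(which(vec)), spec = spec)
    })
  })
}

# Ancestor and lca tables of a small nested-list species tree.
oc_stree_tables <- function(stree) {
  parent <- integer(0); depth <- integer(0); label <- character(0)
  rec <- function(node, par, d) {
    i <- length(parent) + 1L
    parent[i] <<- par; depth[i] <<- d
    label[i] <<- if (!is.null(node$leaf)) node$leaf else NA_character_
    if (!is.null(node$children)) for (ch in node$children) rec(ch, i, d + 1L)
  }
  rec(stree, 0L, 0L)
  nn <- length(parent)
  anc <- matrix(FALSE, nn, nn)
  for (b in seq_len(nn)) {
    x <- b
    while (x > 0L) {
      anc[x, b] <- TRUE
      x <- parent[x]
    }
  }
  lca <- matrix(0L, nn, nn)
  for (a in seq_len(nn)) {
    for (b in seq_len(nn)) {
      x <- a; y <- b
      while (depth[x] > depth[y]) x <- parent[x]
      while (depth[y] > depth[x]) y <- parent[y]
      while (x != y) { x <- parent[x]; y <- parent[y] }
      lca[a, b] <- x
    }
  }
  leaves <- which(!is.na(label))
  list(anc = anc, lca = lca,
       leaf_id = stats::setNames(leaves, label[leaves]))
}

# Node-wise consistency of one DS-tree profile given the species-tree
# leaf id of each gene.
oc_prof_consistent <- function(prof, gene_leaf, tab) {
  for (groups in prof$spec) {
    lcas <- vapply(groups, function(gidx) {
      ids <- unique(gene_leaf[gidx])
      Reduce(function(a, b) tab$lca[a, b], ids)
    }, 0L)
    k <- length(lcas)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        a <- lcas[i]; b <- lcas[j]
        if (a == b || tab$anc[a, b] || tab$anc[b, a]) return(FALSE)
      }
    }
  }
  TRUE
}

# For genes 1..n with species block map `spmap` (integer per gene): the
# species trees on the blocks and, per tree, the set of orthology masks
# achievable by a DS-tree consistent with that tree. Cached.
oc_consistent_sets <- function(n, spmap) {
  key <- paste0("cons", n, "_", paste(spmap, collapse = ""))
  oc_memo(key, {
    k <- max(spmap)
    sp_labels <- paste0("S", seq_len(k))
    strees <- all_rooted_trees(sp_labels)
    profs <- oc_ds_profiles(n)
    sets <- lapply(strees, function(st) {
      tab <- oc_stree_tables(st)
      gene_leaf <- unname(tab$leaf_id[sp_labels[spmap]])
      ok <- vapply(profs, oc_prof_consistent, logical(1L),
                   gene_leaf = gene_leaf, tab = tab)
      sort(unique(vapply(profs[ok], `[[`, 0L, "mask")))
    })
    list(strees = strees, sets = sets,
         free = sort(unique(unlist(sets, use.names = FALSE))))
  })
}

# Random (Emask, Umask) over the cross-species pair positions of a species
# map, with |U| capped. Same-species pairs stay paralogy non-edges.
oc_random_masks <- function(n, spmap, max_u = 4L) {
  pm <- oc_pairs(n)
  cross <- which(spmap[pm[, 1L]] != spmap[pm[, 2L]])
  nu <- sample(0:min(max_u, length(cross)), 1L)
  upos <- if (nu > 0L) sample(cross, nu) else integer(0)
  rest <- setdiff(cross, upos)
  epos <- rest[stats::runif(length(rest)) < 0.5]
  c(E = oc_bits_mask(epos), U = oc_bits_mask(upos))
}

# Family for genes g1..gn with species blocks spmap.
oc_family <- function(n, spmap) {
  gene_family(paste0("g", seq_len(n)), paste0("S", spmap))
}

# ---- misc random generators ----------------------------------------------

# Random nested-list DS-tree on the given leaves (random recursive
# partition shape, random event labels).
oc_random_ds_tree <- function(genes, p_spec = 0.5) {
  if (length(genes) == 1L) return(leaf_node(genes))
  k <- sample(2:min(length(genes), 3L), 1L)
  blocks <- split(sample(genes), sort(rep_len(seq_len(k), length(genes))))
  inner_node(lapply(blocks, oc_random_ds_tree, p_spec = p_spec),
             if (stats::runif(1L) < p_spec) "S" else "D")
}

# A species map for a DS-tree under which no same-species pair is
# orthologous (the standing trivial-paralogy assumption): start with one
# species per gene and randomly merge species classes that are pairwise
# paralogous in the tree.
oc_valid_species_map <- function(tree, merges = 6L) {
  genes <- sort(tree_leaves(tree))
  M <- orthology_matrix(tree)
  cls <- seq_along(genes)
  for (t in seq_len(merges)) {
    ids <- unique(cls)
    if (length(ids) < 2L) break
    pick <- sample(ids, 2L)
    a <- genes[cls == pick[1L]]
    b <- genes[cls == pick[2L]]
    if (!any(M[a, b])) cls[cls == pick[2L]] <- pick[1L]
  }
  stats::setNames(paste0("s", match(cls, unique(cls))), genes)
}
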