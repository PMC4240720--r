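# Synthetic ground truth: a random species tree, a duplication-loss gene
# history evolved along it, the full constraint graph the history induces,
# and a degraded observation of that graph (pairs masked to unknown and,
# optionally, known relations flipped). Every quantity is reproducible
# from a single seed; topology, history, masking and flipping each draw
# from their own derived stream so that, e.g., changing the masking
# fraction leaves the underlying history untouched.

#' Simulation configuration
#'
#' @param n_species number of extant species (>= 1); the species tree is a
#'   random binary rooted topology built by sequential joins.
#' @param dup_prob per-lineage probability of a duplication event on a
#'   branch (each duplicate continues independently, so copy counts follow
#'   a branching process).
#' @param loss_prob per-lineage probability of extinction on a branch.
#' @param mask_frac fraction of cross-species gene pairs whose relation is
#'   hidden (moved to the unknown set U) in the emitted graph.
#' @param flip_frac fraction of the remaining known cross-species pairs
#'   whose relation is inverted (orthology <-> paralogy); used to
#'   manufacture unsatisfiable or inconsistent instances. Flips never touch
#'   masked pairs or same-species pairs.
#' @param seed integer seed; all randomness derives from it.
#' @param max_genes hard cap on the number of extant genes (guards the
#'   branching process).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 5L, dup_prob = 0.2, loss_prob = 0.1,
                       mask_frac = 0, flip_frac = 0, seed = 1L,
                       max_genes = 5000L) {
  stopifnot(n_species >= 1L,
            dup_prob >= 0, dup_prob <= 1,
            loss_prob >= 0, loss_prob <= 1,
            mask_frac >= 0, mask_frac <= 1,
            flip_frac >= 0, flip_frac <= 1)
  structure(list(n_species = as.integer(n_species), dup_prob = dup_prob,
                 loss_prob = loss_prob, mask_frac = mask_frac,
                 flip_frac = flip_frac, seed = as.integer(seed),
                 max_genes = as.integer(max_genes)),
            class = "sim_config")
}

# Derived sub-stream seeds, kept inside 32-bit range.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 104729) %% 2147483647)
}

#' Random rooted binary species tree
#'
#' Sequentially joins uniformly chosen lineage pairs, giving labels
#' `s1..sk`. Uses the current RNG state.
#'
#' @param n_species number of leaves (>= 1).
#' @return a nested-list species tree.
#' @export
random_species_tree <- function(n_species) {
  labels <- paste0("s", seq_len(n_species))
  pool <- lapply(labels, leaf_node)
  while (length(pool) > 1L) {
    pick <- sample.int(length(pool), 2L)
    joined <- inner_node(pool[pick])
    pool <- c(pool[-pick], list(joined))
  }
  pool[[1L]]
}

# Evolve one gene lineage entering the branch above `snode`. Returns a
# gene subtree or NULL (lineage lost). `st` carries the per-species gene
# counters and the global copy cap.
sim_branch <- function(snode, dup_prob, loss_prob, st) {
  if (stats::runif(1L) < loss_prob) return(NULL)
  if (st$count < st$max_genes && stats::runif(1L) < dup_prob) {
    a <- sim_branch(snode, dup_prob, loss_prob, st)
    b <- sim_branch(snode, dup_prob, loss_prob, st)
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    return(inner_node(list(a, b), "D"))
  }
  sim_at_node(snode, dup_prob, loss_prob, st)
}

sim_at_node <- function(snode, dup_prob, loss_prob, st) {
  if (is_leaf_node(snode)) {
    sp <- snode$leaf
    st$per_species[[sp]] <- (st$per_species[[sp]] %||% 0L) + 1L
    st$count <- st$count + 1L
    return(leaf_node(sprintf("g%d@%s", st$per_species[[sp]], sp)))
  }
  kids <- Filter(Negate(is.null),
                 lapply(snode$children, sim_branch,
                        dup_prob = dup_prob, loss_prob = loss_prob, st = st))
  if (length(kids) == 0L) return(NULL)
  if (length(kids) == 1L) return(kids[[1L]])  # speciation unobserved: suppress
  inner_node(kids, "S")
}

#' Simulate a gene family instance
#'
#' Generates a species tree, evolves a duplication-loss history along it
#' (so the history is consistent with the species tree by construction),
#' reads off the full constraint graph the history induces, and degrades
#' it by masking and flipping as configured. If losses wipe out every
#' lineage the history is retried a bounded number of times.
#'
#' @param config a [sim_config()].
#' @return a `sim_instance` list with `species_tree`, `history` (DS-tree),
#'   `family`, `truth` (the induced full constraint graph), `graph` (the
#'   masked/flipped observation) and `config`.
#' @export
simulate_instance <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sub_seed(config$seed, 1L))
  stree <- random_species_tree(config$n_species)

  set.seed(sub_seed(config$seed, 2L))
  history <- NULL
  for (attempt in seq_len(100L)) {
    st <- new.env(parent = emptyenv())
    st$per_species <- list()
    st$count <- 0L
    st$max_genes <- config$max_genes
    history <- sim_branch(stree, config$dup_prob, config$loss_prob, st)
    if (!is.null(history)) break
  }
  if (is.null(history)) {
    stop("all gene lineages were lost in 100 attempts; lower loss_prob")
  }

  genes <- sort(tree_leaves(history))
  species <- sub("^.*@", "", genes)
  family <- gene_family(genes, species)

  M <- orthology_matrix(history)
  keys <- all_pair_keys(genes)
  km <- pair_unkey(keys)
  orth <- M[km]
  cross <- unname(family$species[km[, 1L]] != family$species[km[, 2L]])
  truth <- structure(list(family = family, E = keys[orth], U = character()),
                     class = "constraint_graph")
  if (any(orth & !cross)) {
    stop("internal error: a history made a same-species pair orthologous")
  }

  set.seed(sub_seed(config$seed, 3L))
  cross_keys <- keys[cross]
  n_mask <- round(config$mask_frac * length(cross_keys))
  masked <- if (n_mask > 0L) sample(cross_keys, n_mask) else character()

  set.seed(sub_seed(config$seed, 4L))
  known_cross <- setdiff(cross_keys, masked)
  n_flip <- round(config$flip_frac * length(known_cross))
  flipped <- if (n_flip > 0L) sample(known_cross, n_flip) else character()

  E_obs <- setdiff(truth$E, masked)
  E_obs <- sort(union(setdiff(E_obs, flipped), setdiff(flipped, truth$E)))
  graph <- structure(list(family = family, E = E_obs, U = sort(masked)),
                     class = "constraint_graph")

  structure(list(species_tree = stree, history = history, family = family,
                 truth = truth, graph = graph, config = config),
            class = "sim_instance")
}

#' @export
print.sim_instance <- function(x, ...) {
  cat("Simulated instance:", length(x$family$genes), "genes,",
      x$config$n_species, "species;",
      length(x$graph$E), "orthology edges,",
      length(x$graph$U), "unknown pairs\n")
  invisible(x)
}
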