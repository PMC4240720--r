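---
title: "Deciding satisfiability and consistency of orthology/paralogy constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding satisfiability and consistency of orthology/paralogy constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthocons)
```

## The problem

Tree-free methods — sequence-similarity clustering, synteny, functional
annotation — produce *pairwise* statements about the genes of a family:
this pair is orthologous (their divergence coincides with a speciation),
that pair is paralogous (their divergence was a duplication). Unlike a
reconciled gene tree, such methods usually do not constrain every pair.
Before using these statements to build or correct trees, one should ask
whether they are jointly possible at all.

`orthocons` represents a constraint set as an edge-bicoloured graph
$R = (V, E, U)$: vertices are genes, $E$ holds known orthology pairs, $U$
holds undecided pairs, and every pair in neither set is a known paralogy.
Two genes of the same species are always paralogs (no speciation separates
them), so same-species orthology is rejected by `validate_constraints()`
and same-species unknowns are resolved to paralogy by
`normalize_constraints()`. Choosing a subset $F \subseteq U$ as orthology
and the rest as paralogy gives a *realization* $R(F)$, a full graph.

Three questions are answered, each with a constructive witness:

1. **Satisfiability** (`build_ds_tree()`): is there an event-labeled gene
   tree (*DS-tree*; every internal node marked duplication or speciation)
   whose induced relation — orthologous iff the pair's lca is a
   speciation — realizes $R$?
2. **Consistency with a given species tree** (`build_consistent_ds_tree()`):
   can that DS-tree additionally be a plausible history under a known
   species tree $S$?
3. **Consistency with an unknown species tree** (`check_cons()`,
   `check_consistency_full()`): does *some* species tree admit such a
   history, and if so, which one?

## Satisfiability: a graph sandwich

A full constraint graph is realizable by a DS-tree exactly when it is
$P_4$-free (a cograph): cograph complement/union structure corresponds
one-to-one with duplication/speciation nodes. For partial graphs the
question becomes a graph sandwich problem — is there a $P_4$-free graph
between $E$ and $E \cup U$? — solved by a cubic recursive disconnection
test:

* if the empty realization $R(\emptyset)$ is disconnected, a duplication
  node may join the components (cross-component pairs become paralogs);
* otherwise, if the complement of the full realization $R(U)$ is
  disconnected, a speciation node may join its components
  (cross-component pairs become orthologs);
* if neither splits a set of two or more genes, every realization of that
  subset is connected with a connected complement, hence contains an
  induced $P_4$: unsatisfiable.

When both splits apply the duplication split is taken first; this is a
pure tie-break for determinism, both orders are correct. The witness is
built exactly as the recursion proceeds, as a non-binary star-join; no
binarization is attempted because any refinement realizes the same
relation. `build_ds_tree()` always re-audits its witness against the
definition before returning, and reports which unknown pairs the witness
realized as orthology so the audit can be repeated externally.

## Consistency with a given species tree

A DS-tree is consistent with $S$ when, for every speciation node and
every two of its children, the $S$-lcas of the children's species sets
are *unrelated* (neither ancestral to the other). Equivalently, $S$
displays every *speciation triplet* of the tree — the species-level
triplet $s(x)s(y)|s(z)$ of every gene triplet $xy|z$ rooted at a
speciation with $s(x) \neq s(y)$. Both predicates are implemented
(`is_consistent()`, methods `"definition"` and `"triplets"`) and tested
for agreement.

One caveat found while validating the equivalence: it can fail for
DS-trees that make two same-species genes orthologous (a speciation node
over two leaves of one species has an empty triplet set but fails the
node-wise test). Such trees violate the standing same-species-paralogy
assumption and can never arise from a valid constraint graph, so the
equivalence holds everywhere the package uses it; degenerate speciation
triplets whose outgroup species repeats a grouped species are emitted and
rejected at the display test, which is what closes the remaining gap.

The decision algorithm modifies the satisfiability recursion in one
place: a speciation node is only allowed when the components of the
complement graph can be grouped into a *speciation partition* — two or
more parts whose species-lcas are pairwise unrelated in $S$. Components
whose lcas lie on a common root path must share a part, so grouping each
component under the shallowest ancestral component-lca (a preorder sweep
of $S$, `find_speciation_partition()`) yields the canonical partition;
by construction its part lcas are the maximal, pairwise-unrelated lca
nodes, so no alternative partitions ever need to be enumerated. The
recursion descends into parts, not raw components; inside a part the
complement stays connected at the next level, so speciation nodes never
stack, and the duplication branch is unchanged. Although the theory
implies a failed duplication branch cannot be rescued (consistency is
inherited by induced subgraphs), the implementation still tries the
speciation branch afterwards — the characterization is an OR of the two
conditions, and the cost is negligible.

## Consistency with an unknown species tree

For a *full* satisfiable graph the mandatory species triplets are exactly
those of induced paths $x\!-\!z\!-\!y$ (edges $zx, zy \in E$, pair $xy$ a
known paralogy, $s(x) \neq s(y)$): the lca of $x,y$ must be a duplication
below the speciation joining them to $z$, forcing $s(x)s(y)|s(z)$. The
graph is consistent iff some species tree displays this set
(`extract_p3()` + `build_species_tree()`). The supertree step is the
classical recursive clustering on the triplet graph (BUILD): components
of the graph linking each triplet's grouped pair become the children
clusters; failure occurs when two or more labels stay in one component.
Species never mentioned fall out as singletons and attach unresolved, so
the output is a least-resolved tree; only *some* displaying tree is
required. Pairs whose relation is unknown are excluded from the forced
set — deciding them later is exactly what the search below does.

With unknowns present the problem is attacked by an exact branch-and-bound
(`check_cons()`): at each node the forced triplets of the current partial
graph must be displayable (BUILD prunes), the partial graph must remain
satisfiable with unknowns as wildcards (the sandwich recursion prunes),
and when no unknowns remain the current graph plus BUILD tree is a
solution. Branching decides one unknown pair, orthology first; unknown
pairs inside an induced $P_4$ of the orthology graph are branched on
first (they are the pairs whose decision is most constrained), ties
lexicographic. The search is worst-case exponential in $|U|$ — the
complexity of this problem is open — so a `max_nodes` cap turns runaway
searches into a typed error (`orthocons_search_limit`), never a wrong
verdict.

`preprocess_forced_edges()` shrinks $U$ before the search: an induced
$P_4$ of the orthology graph (or of the complement of the full
realization) whose four vertices span exactly one unknown pair can only
be destroyed by deciding that pair one way; an unknown pair closing an
$E$-path is forced to orthology when its paralogy completion would create
a triplet clashing with an already-forced one (or an undisplayable
repeated-species triplet). A pair forced both ways proves inconsistency
outright. Preprocessing is verdict-preserving and can be disabled.

Two families are consistent unconditionally and short-circuit everything:
orthology-only constraint sets (per-species duplication stars under one
speciation root, star species tree) and paralogy-only sets (one
duplication star, star species tree); `orthology_only_witness()` and
`paralogy_only_witness()` return these constructions.

Combining two full prediction sets of different stringency — keep
relations on which both agree, mark disagreements unknown
(`combine_graphs()`) — is the intended source of partial graphs in
practice.

## The simulator

`simulate_instance()` provides ground truth: a random binary species tree
on `n_species` leaves (uniform sequential joins); one gene lineage
evolved from the root, where on every branch a lineage is lost with
probability `loss_prob` or duplicated with probability `dup_prob` (each
copy continuing independently — a branching process, so gene counts have
heavy tails), and speciates at every species-tree node. Unobserved
speciations (all but one child lineage lost) are suppressed, so the
history is a valid DS-tree consistent with the species tree by
construction. The induced full constraint graph is then degraded:
`mask_frac` of the cross-species pairs are moved to $U$, and `flip_frac`
of the remaining known cross-species pairs are inverted to manufacture
broken instances. Same-species pairs are never masked or flipped — their
paralogy is trivially known. Topology, history, masking and flipping draw
from separate seeded streams, so changing `mask_frac` leaves the history
untouched.

Defaults (`n_species = 5`, `dup_prob = 0.2`, `loss_prob = 0.1`) give
families of roughly 5-40 genes with a realistic mix of duplication
clusters, chosen once as typical of curated vertebrate gene families; no
published generative model exists for these histories, so the birth
process is this package's own stand-in and is not calibrated to any
database. What the simulator does *not* emulate: sequence evolution and
inference noise (flips are adversarial, not similarity-driven), branch
lengths, rate variation, and horizontal transfer (out of scope
throughout). Passing closure tests on simulated data therefore shows
algorithmic correctness, not robustness to real predictor error profiles.

## Numerical and design choices

* Pairs are stored with the lexicographically smaller gene first;
  components, partition parts and witness children are ordered by their
  smallest member — all output is byte-stable across runs.
* Tree equality is label-isomorphism ignoring child order; restriction
  keeps the lca of the kept leaves as root and suppresses other unary
  nodes, and a star restriction does not display a binary triplet.
* Connected components use a plain BFS over logical adjacency matrices:
  the recursion's inner search is part of the algorithm itself and sits
  in a hot loop (the validation suite calls it tens of thousands of
  times), where the constant factor of building graph objects would
  dominate.
* On-disk formats differ deliberately from the in-memory model: files
  list paralogy explicitly and leave unknowns implicit, memory does the
  reverse; readers and writers convert losslessly. DS-trees serialize as
  Newick with `S`/`D` internal labels or NHX `Ev=` tags; both dialects
  are read.
* Every positive verdict is re-audited internally (satisfaction, and
  consistency where applicable) before being returned; an audit failure
  is an internal error, never a silent wrong answer.

## Validation strategy and problem sizes

The test suite pins each decision route to an independent exhaustive
oracle: satisfiability against enumeration of all realizations with a
4-subset $P_4$ scan — exhaustively over all $3^{10}$ edge-bicolourings of
five genes and all smaller vertex sets, plus random graphs on 6-7 genes;
both consistency problems against enumeration of all DS-trees (all
multifurcating shapes times all event labelings) and, for the unknown-$S$
case, all rooted species trees — exhaustively over all gene-to-species
partitions into at most four blocks and all species trees on the blocks,
with all graphs up to three genes and fixed-seed random graph samples
(unknowns capped at four) for four and five genes. The remaining checks
run hundreds of simulated instances per property (witness audits,
masking closure, heritability, predicate equivalence) and one ~380-gene
instance as a guard against accidental exponential behaviour in the
polynomial routes. These sizes were chosen so the whole suite exercises
every code path at interpreted-R speed; the oracles themselves, not the
sizes, carry the evidential weight.

## Limitations

* `check_cons()` is practical only for modest unknown sets (tens of
  pairs, problem-dependent); this mirrors the open complexity status of
  the underlying question, not an implementation shortcut.
* Weighted or probabilistic constraints, directed relations, horizontal
  transfer, reconciliation costs and gene-tree editing are out of scope.
* The species-tree output of `build_species_tree()` is least-resolved
  rather than canonical: distinct runs of *different* inputs displaying
  the same triplets may return different (equally valid) trees.
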