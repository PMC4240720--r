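# orthocons

Deciding whether a set of pairwise orthology/paralogy statements about a
gene family is *possible* — and exhibiting the evolutionary scenario that
makes it so.

Tree-free orthology predictors (similarity clustering, synteny, function)
constrain some gene pairs as orthologs and some as paralogs, and say
nothing about the rest. `orthocons` models such a partial constraint set
as an edge-bicoloured graph **R = (V, E, U)**: genes as vertices,
orthology edges *E*, unknown pairs *U*, and known paralogy as the
remaining non-edges. It answers three questions, each with a constructive,
internally audited witness:

1. **Satisfiability** — is there an event-labeled gene tree (a *DS-tree*,
   every internal node marked duplication or speciation) inducing the
   known relations? Pairs are orthologous exactly when their least common
   ancestor is a speciation node. A full graph is realizable iff it is
   P4-free (a cograph); a partial graph is a graph-sandwich instance,
   solved in O(n³) by a recursive disconnection test (`build_ds_tree()`):
   a disconnected empty realization licenses a duplication root, a
   disconnected complement of the full realization licenses a speciation
   root, and if neither splits, the instance is unsatisfiable.
2. **Consistency with a given species tree S**
   (`build_consistent_ds_tree()`) — same recursion, but a speciation node
   is only created above a *speciation partition*: groups of complement
   components whose species-lcas are pairwise unrelated in S.
3. **Consistency with an unknown species tree** (`check_cons()`) — for
   full graphs, the induced paths x–z–y (edges zx, zy; non-edge xy) force
   the species triplets s(x)s(y)|s(z); the graph is consistent iff some
   species tree displays them all, decided by Aho-style supertree
   assembly (`build_species_tree()`). With unknowns present, an exact
   branch-and-bound over U with triplet and satisfiability pruning and
   forced-edge preprocessing (`preprocess_forced_edges()`) finds a
   consistent realization or proves there is none.

A duplication–loss simulator (`simulate_instance()`) generates ground
truth histories with masking/corruption, and `brute_*` functions provide
exhaustive reference verdicts at toy sizes. `combine_graphs()` merges two
full prediction sets of different stringency into a robust partial graph
(agreements kept, disagreements marked unknown).

## Worked example

Five genes in species A, B, C (twice) and E; the predictor calls e1
orthologous to everything, a1–b1 orthologous, leaves b1–c1 undecided, and
the remaining pairs paralogous:

```r
library(orthocons)
fam <- gene_family(c("a1","b1","c1","c2","e1"), c("A","B","C","C","E"))
r <- constraint_graph(fam,
  orthology = rbind(c("a1","b1"), c("a1","e1"), c("b1","e1"),
                    c("c1","e1"), c("c2","e1")),
  unknown   = rbind(c("b1","c1")))

build_ds_tree(r)
#> Status: satisfiable
#> Witness DS-tree: (((a1,b1)S,c1,c2)D,e1)S;

extract_p3(r)
#>      x   y   z
#> [1,] "A" "C" "E"
#> [2,] "B" "C" "E"

check_cons(r)
#> Status: consistent
#> Species tree: (((A,C),B),E);
#> Witness DS-tree: ((((a1,c1)D,b1)S,c2)D,e1)S;
```

The satisfiability witness realizes the constraints with b1–c1 as
paralogs. The induced paths through e1 force the species triplets AC|E
and BC|E (a1 and c1, resp. b1 and c2, must have split by a duplication
*below* the speciation that separates them from e1), and the search finds
a species tree displaying both, plus a history consistent with it — this
time realizing b1–c1 as orthologs. Against an incompatible species tree
the same constraints are refused:

```r
build_consistent_ds_tree(r, read_species_tree(textConnection("((A,C),(B,E));")))
#> Status: inconsistent
#> Failed on gene subset: a1, b1, c1, c2, e1
```

A shell interface with subcommands `sat`, `cons-with-tree`, `cons` and
`simulate` lives in `inst/cli/orthocons-cli.R` (exit codes: 0 positive
verdict, 1 negative, 2 input error, 3 search cap).

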