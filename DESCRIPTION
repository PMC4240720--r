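Package: orthocons
Title: Satisfiability and Consistency of Partial Orthology and Paralogy
    Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decide whether a partial set of pairwise orthology and
    paralogy constraints over a gene family can be realized by an
    event-labeled gene tree (satisfiability), whether such a tree can be
    made consistent with a given species tree, and whether some species
    tree exists at all (consistency). Implements the graph-sandwich
    recursion for P4-free realizations, speciation partitions for a fixed
    species tree, forced-triplet extraction with Aho-style supertree
    assembly for an unknown species tree, a branch-and-bound completion
    search with forced-edge preprocessing, exhaustive reference oracles
    for validation, and a duplication-loss gene history simulator for
    generating benchmark instances.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
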