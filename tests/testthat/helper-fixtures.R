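# Small deterministic fixtures used across test files.

# n genes a, b, c, ... each in its own species.
fam_distinct <- function(n) {
  gene_family(letters[seq_len(n)], paste0("sp", seq_len(n)))
}

# Pair matrix helper: rbind of 2-vectors written compactly.
pairs <- function(...) {
  do.call(rbind, list(...))
}

# The minimal forced-triplet instance: three genes in species a, d, e with
# orthology edges ga-ge and gd-ge and a paralogy non-edge ga-gd. Every
# satisfying DS-tree has the speciation triplet ad|e.
forced_ade_graph <- function() {
  fam <- gene_family(c("ga", "gd", "ge"), c("a", "d", "e"))
  constraint_graph(fam, orthology = pairs(c("ga", "ge"), c("gd", "ge")))
}

nwk <- function(text) orthocons:::newick_to_tree(text)
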