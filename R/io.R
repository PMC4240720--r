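# Plain-text interchange formats. Relations file: TSV with columns gene1,
# gene2, relation in {orthologs, paralogs}; pairs absent from the file are
# unknown. Species map: TSV with columns gene, species. '#' comment lines
# and an optional header are skipped. Note the deliberate encoding
# difference: on disk paralogy is explicit and unknown implicit, while in
# memory paralogy is the implicit non-edge and unknowns are explicit (U);
# the readers and writers convert losslessly.

read_tsv_lines <- function(path, ncol, what) {
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) != ncol)
  if (length(bad) > 0L) {
    stop(sprintf("%s: line %d is malformed (expected %d tab-separated fields)",
                 what, keep[bad[1L]], ncol))
  }
  list(fields = fields, lines = keep)
}

#' Read a gene-to-species map (TSV: gene, species)
#'
#' @param path input file; `#` comments and an optional
#'   `gene<TAB>species` header are skipped.
#' @return a [gene_family()].
#' @export
read_species_map <- function(path) {
  p <- read_tsv_lines(path, 2L, "species map")
  m <- do.call(rbind, p$fields)
  if (nrow(m) > 0L && tolower(m[1L, 1L]) == "gene" && tolower(m[1L, 2L]) == "species") {
    m <- m[-1L, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("species map is empty")
  if (anyDuplicated(m[, 1L])) {
    dup <- m[duplicated(m[, 1L]), 1L][1L]
    stop("species map lists gene more than once: ", dup)
  }
  gene_family(m[, 1L], m[, 2L])
}

#' Write a gene-to-species map
#' @param family a [gene_family()].
#' @param path output file.
#' @export
write_species_map <- function(family, path) {
  writeLines(c("gene\tspecies",
               paste(family$genes, unname(family$species[family$genes]),
                     sep = "\t")),
             path)
}

#' Read a constraint graph from a relations file
#'
#' Each line constrains one pair: `gene1<TAB>gene2<TAB>relation` with
#' relation `orthologs` or `paralogs`. Pairs absent from the file are
#' unknown; same-species pairs are always resolved to paralogy. A pair
#' listed twice with conflicting relations is an error, as is a gene
#' absent from the species map.
#'
#' @param path relations TSV file.
#' @param family a [gene_family()], e.g. from [read_species_map()].
#' @return a normalized [constraint_graph()].
#' @export
read_relations <- function(path, family) {
  p <- read_tsv_lines(path, 3L, "relations file")
  m <- if (length(p$fields) == 0L) {
    matrix(character(), 0L, 3L)
  } else {
    do.call(rbind, p$fields)
  }
  lines <- p$lines
  if (nrow(m) > 0L && tolower(m[1L, 3L]) == "relation") {
    m <- m[-1L, , drop = FALSE]
    lines <- lines[-1L]
  }
  rel <- tolower(m[, 3L, drop = TRUE])
  ok <- rel %in% c("orthologs", "paralogs")
  if (any(!ok)) {
    stop(sprintf("relations file: line %d has unknown relation '%s'",
                 lines[which(!ok)[1L]], m[which(!ok)[1L], 3L]))
  }
  unknown_gene <- !(m[, 1L] %in% family$genes) | !(m[, 2L] %in% family$genes)
  if (any(unknown_gene)) {
    i <- which(unknown_gene)[1L]
    stop(sprintf("relations file: line %d names a gene missing from the species map",
                 lines[i]))
  }
  self <- m[, 1L] == m[, 2L]
  if (any(self)) {
    stop(sprintf("relations file: line %d pairs a gene with itself",
                 lines[which(self)[1L]]))
  }
  keys <- if (nrow(m) == 0L) character() else pair_key(m[, 1L], m[, 2L])
  for (k in unique(keys)) {
    rels <- unique(rel[keys == k])
    if (length(rels) > 1L) {
      p2 <- pair_unkey(k)
      stop(sprintf("relations file: pair {%s,%s} listed as both orthologs and paralogs",
                   p2[1L], p2[2L]))
    }
  }
  E <- unique(keys[rel == "orthologs"])
  P <- unique(keys[rel == "paralogs"])
  all_keys <- all_pair_keys(family$genes)
  U <- setdiff(all_keys, union(E, P))
  graph <- structure(list(family = family, E = sort(E), U = sort(U)),
                     class = "constraint_graph")
  normalize_constraints(graph)
}

#' Write a constraint graph to a relations file
#'
#' Orthology edges are written as `orthologs` lines and paralogy non-edges
#' as explicit `paralogs` lines; unknown pairs are omitted, so a write/read
#' round trip reproduces E, U and the non-edges exactly.
#'
#' @param graph a [constraint_graph()].
#' @param path output file.
#' @export
write_relations <- function(graph, path) {
  nonedges <- setdiff(all_pair_keys(graph$family$genes),
                      union(graph$E, graph$U))
  fmt <- function(keys, rel) {
    if (length(keys) == 0L) return(character())
    m <- pair_unkey(sort(keys))
    paste(m[, 1L], m[, 2L], rel, sep = "\t")
  }
  writeLines(c("gene1\tgene2\trelation",
               fmt(graph$E, "orthologs"),
               fmt(nonedges, "paralogs")),
             path)
}
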