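#' Enumerate all embeddings of a motif in a network
#'
#' An embedding is a set of network edge indices whose edge-subgraph is
#' isomorphic to the motif (the identity of an embedding is its edge set, not
#' the node mapping, so symmetric patterns such as the bifan are counted once
#' per edge set). Matching is non-induced by default: extra network edges
#' among the matched nodes do not disqualify an embedding. The number of
#' embeddings is the classical F1 motif count.
#'
#' Subgraph matching is delegated to igraph's LAD solver; node mappings are
#' collapsed to distinct edge-index sets and returned in lexicographic order,
#' so the output is deterministic.
#'
#' @param network a [pomoc_network()].
#' @param motif a [motif_pattern()].
#' @param induced if `TRUE`, only induced matches are kept (the matched node
#'   set must carry exactly the motif's edges).
#' @return list of sorted integer vectors of 1-based edge indices, ordered
#'   lexicographically; empty list when the motif does not occur.
#' @examples
#' tri <- pomoc_network(data.frame(source = c("u", "v", "w"),
#'                                 target = c("v", "w", "u")))
#' enumerate_embeddings(tri, motif_pattern("cascade"))
#' @export
enumerate_embeddings <- function(network, motif, induced = FALSE) {
  m <- nrow(network$edges)
  if (m < nrow(motif$edges) || length(network$nodes) < length(motif$nodes)) {
    return(list())
  }
  g <- as_igraph_network(network)
  pat <- as_igraph_motif(motif)
  maps <- igraph::subgraph_isomorphisms(pat, g, method = "lad",
                                        induced = induced)
  if (!length(maps)) return(list())
  # motif edge endpoints as positions in the pattern vertex order
  pe <- igraph::as_edgelist(pat, names = FALSE)
  esets <- lapply(maps, function(mp) {
    mp <- as.integer(mp)
    vp <- as.vector(rbind(mp[pe[, 1L]], mp[pe[, 2L]]))
    sort(as.integer(igraph::get_edge_ids(g, vp)))
  })
  unique_embeddings(esets)
}

# drop duplicate edge sets and order lexicographically
unique_embeddings <- function(esets) {
  if (!length(esets)) return(list())
  keys <- vapply(esets, paste, "", collapse = ",")
  esets <- esets[!duplicated(keys)]
  k <- length(esets[[1L]])
  mat <- matrix(unlist(esets), ncol = k, byrow = TRUE)
  ord <- do.call(order, lapply(seq_len(k), function(j) mat[, j]))
  esets[ord]
}

#' F1 motif count (unlimited overlap)
#'
#' The F1 measure counts every embedding of the motif, ignoring edge sharing;
#' it equals the partially overlapping count when all capacities are
#' unbounded.
#'
#' @inheritParams enumerate_embeddings
#' @return non-negative integer.
#' @export
count_f1 <- function(network, motif, induced = FALSE) {
  length(enumerate_embeddings(network, motif, induced = induced))
}
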