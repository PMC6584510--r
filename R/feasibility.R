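#' Per-edge usage of an embedding subset
#'
#' Entry `i` counts the embeddings in `subset` that contain edge `i`. The
#' entries always sum to (motif edge count) x (number of embeddings).
#'
#' @param subset list of embeddings (integer vectors of edge indices).
#' @param m total number of network edges (length of the result).
#' @return integer vector of length `m`.
#' @export
usage_vector <- function(subset, m) {
  if (!length(subset)) return(integer(m))
  tabulate(unlist(subset, use.names = FALSE), nbins = m)
}

#' Is an embedding subset feasible under edge capacities?
#'
#' A subset is feasible when no edge appears in more embeddings than its
#' capacity; unbounded (`Inf`) capacities are always satisfied. Feasibility
#' is downward closed: every subset of a feasible set is feasible.
#'
#' @inheritParams usage_vector
#' @param capacity per-edge capacity vector (positive integers or `Inf`).
#' @return logical scalar.
#' @export
is_feasible <- function(subset, capacity) {
  all(usage_vector(subset, length(capacity)) <= capacity)
}

#' Embeddings guaranteed to belong to an optimal solution
#'
#' An embedding is guaranteed when each of its edges has enough capacity for
#' every embedding using that edge, i.e. its total usage over the *complete*
#' embedding set does not exceed the capacity. Such embeddings can be fixed
#' into the solution without loss of optimality: adding one to any feasible
#' subset keeps the subset feasible.
#'
#' @param embeddings the complete embedding set (as from
#'   [enumerate_embeddings()]).
#' @param capacity per-edge capacity vector.
#' @return integer vector of positions in `embeddings` that are guaranteed.
#' @export
guaranteed_embeddings <- function(embeddings, capacity) {
  total <- usage_vector(embeddings, length(capacity))
  which(vapply(embeddings, function(h) all(total[h] <= capacity[h]), NA))
}

#' Build the overlap graph of an embedding set
#'
#' The overlap graph has one vertex per embedding and an undirected edge
#' between two vertices whenever their embeddings share at least one network
#' edge. A maximum independent set of this graph is the F2 (edge-disjoint)
#' count; the capacity-constrained search operates on the same structure.
#'
#' @param embeddings list of embeddings (integer edge-index vectors).
#' @param m number of network edges; inferred from the embeddings if missing.
#' @return object of class `pomoc_overlap` with elements `n` (vertex count),
#'   `embeddings`, `incidence` (for each network edge, the ids of embeddings
#'   containing it) and `adj` (sorted neighbor lists).
#' @export
build_overlap_graph <- function(embeddings, m = NULL) {
  n <- length(embeddings)
  if (is.null(m)) m <- if (n) max(unlist(embeddings)) else 0L
  incidence <- vector("list", m)
  for (i in seq_len(n)) {
    for (e in embeddings[[i]]) incidence[[e]] <- c(incidence[[e]], i)
  }
  adj <- lapply(seq_len(n), function(i) {
    nb <- unlist(incidence[embeddings[[i]]], use.names = FALSE)
    sort(unique(nb[nb != i]))
  })
  structure(list(n = n, embeddings = embeddings, incidence = incidence,
                 adj = adj),
            class = "pomoc_overlap")
}

#' @export
print.pomoc_overlap <- function(x, ...) {
  ne <- sum(lengths(x$adj)) / 2
  cat(sprintf("Overlap graph: %d embeddings, %d overlap edges\n", x$n, ne))
  invisible(x)
}

#' Per-node motif participation counts
#'
#' For every network node, counts the solution embeddings whose edges touch
#' that node. Used to profile how motif load distributes over genes.
#'
#' @param solution a `pomoc_solution` (from [pomoc()]) or a plain list of
#'   embeddings.
#' @param network the [pomoc_network()] the embeddings refer to.
#' @return named integer vector over all network nodes.
#' @export
per_gene_motif_counts <- function(solution, network) {
  embeddings <- if (inherits(solution, "pomoc_solution")) solution$embeddings else solution
  counts <- integer(length(network$nodes))
  names(counts) <- network$nodes
  src <- network$edges$source
  tgt <- network$edges$target
  for (h in embeddings) {
    touched <- unique(c(src[h], tgt[h]))
    counts[touched] <- counts[touched] + 1L
  }
  counts
}
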