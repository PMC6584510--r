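#' Construct a capacity-annotated directed network
#'
#' A `pomoc_network` holds an ordered node set, an ordered directed edge list
#' (edges are indexed 1..m and index `i` always refers to the same
#' source/target pair), and a per-edge capacity vector. The capacity of an
#' edge is the maximum number of motif embeddings that edge may belong to
#' simultaneously; `Inf` marks an unbounded edge (the F1 regime).
#'
#' @param edges two-column data frame (or matrix) of `source`, `target` node
#'   labels, one row per directed edge, in the order that defines the edge
#'   indices.
#' @param capacity numeric vector of per-edge capacities (positive integers or
#'   `Inf`), recycled if length 1. Defaults to `Inf` for every edge.
#' @param nodes optional character vector fixing the node order; defaults to
#'   the nodes in order of first appearance in `edges`. Extra labels are kept
#'   as isolated nodes.
#' @param validate if `TRUE` (default), invalid networks raise an error.
#' @return an object of class `pomoc_network` with elements `nodes`, `edges`
#'   (data frame with character columns `source`, `target`) and `capacity`.
#' @seealso [validate_network()], [read_network()], [generate_network()]
#' @examples
#' net <- pomoc_network(data.frame(source = c("a", "b"), target = c("b", "c")),
#'                      capacity = c(1, 2))
#' net
#' @export
pomoc_network <- function(edges, capacity = NULL, nodes = NULL, validate = TRUE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("'edges' needs source and target columns")
  edges <- data.frame(source = as.character(edges[[1L]]),
                      target = as.character(edges[[2L]]),
                      stringsAsFactors = FALSE)
  m <- nrow(edges)
  if (is.null(capacity)) capacity <- rep(Inf, m)
  if (length(capacity) == 1L) capacity <- rep(as.numeric(capacity), m)
  capacity <- as.numeric(capacity)
  if (is.null(nodes)) {
    nodes <- unique(c(rbind(edges$source, edges$target)))
  } else {
    nodes <- unique(c(as.character(nodes), edges$source, edges$target))
  }
  net <- structure(list(nodes = nodes, edges = edges, capacity = capacity),
                   class = "pomoc_network")
  if (validate) {
    bad <- validate_network(net)
    if (length(bad)) stop("invalid network: ", paste(bad, collapse = "; "))
  }
  net
}

#' Check the structural invariants of a directed network
#'
#' Reports (rather than raises) every violated invariant: duplicated
#' source/target pairs, self-loops, capacity entries that are not positive
#' integers or `Inf`, and a capacity vector whose length differs from the
#' edge count.
#'
#' @param network a [pomoc_network()] object.
#' @return character vector of violation descriptions; empty when the network
#'   is valid.
#' @export
validate_network <- function(network) {
  out <- character(0)
  e <- network$edges
  m <- nrow(e)
  if (length(network$capacity) != m) {
    out <- c(out, sprintf("capacity vector has length %d but there are %d edges",
                          length(network$capacity), m))
  }
  loops <- which(e$source == e$target)
  if (length(loops)) {
    out <- c(out, sprintf("self-loop at edge index %d (%s)", loops,
                          e$source[loops]))
  }
  key <- paste(e$source, e$target, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    out <- c(out, sprintf("duplicated edge %s -> %s at index %d",
                          e$source[dup], e$target[dup], dup))
  }
  cap <- network$capacity[seq_len(min(m, length(network$capacity)))]
  badcap <- which(!is.infinite(cap) & (is.na(cap) | cap < 1 | cap != floor(cap)))
  if (length(badcap)) {
    out <- c(out, sprintf("capacity at edge index %d is %s (must be a positive integer or Inf)",
                          badcap, format(cap[badcap])))
  }
  if (!all(c(e$source, e$target) %in% network$nodes)) {
    out <- c(out, "edge endpoints missing from the node set")
  }
  out
}

#' @export
print.pomoc_network <- function(x, ...) {
  m <- nrow(x$edges)
  cat(sprintf("Directed network: %d nodes, %d edges\n", length(x$nodes), m))
  if (m > 0L) {
    cap <- ifelse(is.infinite(x$capacity), "Inf", format(x$capacity))
    shown <- min(m, 10L)
    for (i in seq_len(shown)) {
      cat(sprintf("  e%d: %s -> %s  (capacity %s)\n", i,
                  x$edges$source[i], x$edges$target[i], cap[i]))
    }
    if (m > shown) cat(sprintf("  ... and %d more edges\n", m - shown))
  }
  invisible(x)
}

# igraph view of a network; vertex i corresponds to network$nodes[i] and
# igraph edge ids coincide with the 1-based edge indices.
as_igraph_network <- function(network) {
  idx <- cbind(match(network$edges$source, network$nodes),
               match(network$edges$target, network$nodes))
  g <- igraph::make_empty_graph(n = length(network$nodes), directed = TRUE)
  igraph::add_edges(g, as.vector(t(idx)))
}
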