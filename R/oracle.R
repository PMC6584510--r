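#' Exact maximum feasible embedding subset (branch and bound)
#'
#' Ground-truth reference for small instances: finds a provably largest
#' feasible subset of the given embeddings by depth-first include/exclude
#' search. Guaranteed embeddings (see [guaranteed_embeddings()]) are fixed
#' up front; the remainder are branched in order of decreasing overlap-graph
#' degree (most-constrained first). A branch is pruned when even taking all
#' remaining embeddings cannot beat the incumbent, or when an inclusion
#' violates a capacity. Among equal-size optima the lexicographically
#' smallest set of embedding indices is returned, so results are
#' reproducible.
#'
#' @param embeddings complete list of embeddings (integer edge-index
#'   vectors).
#' @param capacity per-edge capacity vector (positive integers or `Inf`).
#' @param max_embeddings refuse instances with more embeddings than this
#'   (default 25); the search is exponential and this oracle is meant for
#'   validation, not scale.
#' @return list with `size` (the true optimum) and `selection` (sorted
#'   positions into `embeddings` of one optimal subset).
#' @examples
#' fx <- fig2_instance()
#' max_feasible_exact(fx$embeddings, fx$network$capacity)$size
#' @export
max_feasible_exact <- function(embeddings, capacity, max_embeddings = 25L) {
  n <- length(embeddings)
  if (n > max_embeddings) {
    stop("oracle bound exceeded: ", n, " embeddings > max_embeddings = ",
         max_embeddings)
  }
  if (!n) return(list(size = 0L, selection = integer(0)))
  guar <- guaranteed_embeddings(embeddings, capacity)
  residual <- capacity - usage_vector(embeddings[guar], length(capacity))
  rest <- setdiff(seq_len(n), guar)
  rest <- rest[vapply(rest, function(i) all(residual[embeddings[[i]]] >= 1), NA)]
  if (length(rest)) {
    overlap <- build_overlap_graph(embeddings[rest], m = length(capacity))
    rest <- rest[order(-lengths(overlap$adj), rest)]
  }
  best_size <- -1L
  best_sel <- integer(0)

  consider <- function(sel) {
    sel <- sort(sel)
    if (length(sel) > best_size ||
        (length(sel) == best_size && lex_less(sel, best_sel))) {
      best_size <<- length(sel)
      best_sel <<- sel
    }
  }

  recurse <- function(pos, chosen, r) {
    if (pos > length(rest)) {
      consider(c(guar, chosen))
      return(invisible())
    }
    if (length(guar) + length(chosen) + (length(rest) - pos + 1L) < best_size) {
      return(invisible())
    }
    i <- rest[pos]
    h <- embeddings[[i]]
    if (all(r[h] >= 1)) {           # include branch first
      r2 <- r
      r2[h] <- r2[h] - 1
      recurse(pos + 1L, c(chosen, i), r2)
    }
    recurse(pos + 1L, chosen, r)    # exclude branch
  }
  recurse(1L, integer(0), residual)
  list(size = best_size, selection = best_sel)
}

# is sorted integer vector a lexicographically smaller than b (same length)?
lex_less <- function(a, b) {
  if (!length(b)) return(FALSE)
  d <- which(a != b)
  length(d) > 0L && a[d[1L]] < b[d[1L]]
}

#' Exact partially overlapping motif count for small instances
#'
#' Convenience wrapper: enumerates the embeddings and routes them through
#' [max_feasible_exact()]. Errors if the instance exceeds the oracle bound.
#'
#' @inheritParams pomoc
#' @param max_embeddings passed to [max_feasible_exact()].
#' @return a `pomoc_solution` with `measure = "exact"`.
#' @export
pomoc_exact <- function(network, motif, capacity = NULL, induced = FALSE,
                        max_embeddings = 25L) {
  if (is.character(motif)) motif <- motif_pattern(motif)
  cap <- if (is.null(capacity)) network$capacity else capacity
  m <- nrow(network$edges)
  if (length(cap) == 1L) cap <- rep(as.numeric(cap), m)
  embeddings <- enumerate_embeddings(network, motif, induced = induced)
  res <- max_feasible_exact(embeddings, cap, max_embeddings = max_embeddings)
  build_solution(list(chosen = res$selection,
                      guaranteed = guaranteed_embeddings(embeddings, cap),
                      iterations = 0L, converged = TRUE),
                 embeddings, cap, network, motif, pomoc_control(seed = 0L),
                 seed = 0L, measure = "exact")
}
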