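#' The built-in worked example
#'
#' A small fully worked instance used throughout the documentation and test
#' suite: a directed network with eight nodes and eight edges (indices
#' e1..e8), edge capacities `C = (1,2,2,2,1,2,2,1)`, and a three-edge motif
#' (`a->b, a->c, b->d`) with exactly six embeddings H1..H6. The instance is
#' a synthetic transcription chosen so that every published property of the
#' original worked example holds and is machine-checked by
#' [validate_fig2()]: the F1 count is 6, the edge-disjoint F2 count is 2,
#' the partially overlapping count under `C` is 4 (attained by
#' {H1, H4, H5, H6}), {H1, H6} uses capacity `(1,1,1,0,0,1,1,1)`,
#' {H2, H5, H6} uses `(1,1,0,2,1,2,1,1)`, {H1, H2} is infeasible through
#' edge e1, and H6 is the only guaranteed embedding.
#'
#' @return list with elements `network` (a [pomoc_network()]), `motif`
#'   (a [motif_pattern()]) and `embeddings` (named list `H1`..`H6` of
#'   edge-index sets, each a sorted integer vector).
#' @examples
#' fx <- fig2_instance()
#' count_f1(fx$network, fx$motif)
#' @export
fig2_instance <- function() {
  network <- pomoc_network(
    data.frame(
      source = c("v1", "v5", "v7", "v3", "v1", "v1", "v5", "v6"),
      target = c("v7", "v3", "v5", "v4", "v8", "v3", "v6", "v2")),
    capacity = c(1, 2, 2, 2, 1, 2, 2, 1))
  motif <- motif_pattern(data.frame(source = c("a", "a", "b"),
                                    target = c("b", "c", "d")),
                         name = "fig2")
  embeddings <- list(H1 = c(1L, 3L, 6L), H2 = c(1L, 4L, 6L),
                     H3 = c(1L, 3L, 5L), H4 = c(2L, 4L, 7L),
                     H5 = c(4L, 5L, 6L), H6 = c(2L, 7L, 8L))
  list(network = network, motif = motif, embeddings = embeddings)
}

#' Machine-check the worked example against its published properties
#'
#' Re-derives every stated fact about the worked instance from scratch and
#' reports each violated assertion; an empty result is the proof that the
#' transcription is faithful. Pass a perturbed instance to verify that the
#' checks have teeth.
#'
#' @param fx instance in the shape returned by [fig2_instance()] (the
#'   default).
#' @return character vector of violated assertions; empty on success.
#' @export
validate_fig2 <- function(fx = fig2_instance()) {
  bad <- character(0)
  chk <- function(ok, what) if (!isTRUE(ok)) bad <<- c(bad, what)
  net <- fx$network
  H <- fx$embeddings
  m <- nrow(net$edges)
  chk(length(net$nodes) == 8L && m == 8L, "network has 8 nodes and 8 edges")
  chk(identical(net$capacity, c(1, 2, 2, 2, 1, 2, 2, 1)),
      "capacity vector is (1,2,2,2,1,2,2,1)")
  found <- enumerate_embeddings(net, fx$motif)
  key <- function(x) vapply(x, paste, "", collapse = ",")
  chk(length(found) == 6L && setequal(key(found), key(H)),
      "enumeration yields exactly the six stored embeddings")
  chk(identical(usage_vector(H[c("H1", "H6")], m),
                c(1L, 1L, 1L, 0L, 0L, 1L, 1L, 1L)),
      "usage of {H1,H6} is (1,1,1,0,0,1,1,1)")
  chk(identical(usage_vector(H[c("H2", "H5", "H6")], m),
                c(1L, 1L, 0L, 2L, 1L, 2L, 1L, 1L)),
      "usage of {H2,H5,H6} is (1,1,0,2,1,2,1,1)")
  chk(is_feasible(H[c("H1", "H6")], net$capacity), "{H1,H6} is feasible")
  chk(!is_feasible(H[c("H1", "H2")], net$capacity) &&
        usage_vector(H[c("H1", "H2")], m)[1L] > net$capacity[1L],
      "{H1,H2} is infeasible through edge e1")
  chk(is_feasible(H[c("H1", "H4", "H5", "H6")], net$capacity),
      "{H1,H4,H5,H6} is feasible")
  chk(identical(names(H)[guaranteed_embeddings(unname(H), net$capacity)], "H6"),
      "H6 is the only guaranteed embedding")
  chk(max_feasible_exact(unname(H), net$capacity)$size == 4L,
      "optimum under C is 4")
  chk(max_feasible_exact(unname(H), rep(1, m))$size == 2L,
      "optimum with all capacities 1 is 2")
  chk(max_feasible_exact(unname(H), rep(Inf, m))$size == 6L,
      "optimum with unbounded capacities is 6")
  bad
}
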