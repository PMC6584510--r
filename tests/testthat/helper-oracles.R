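# Independent brute-force oracles used to validate the package's
# implementations on tiny instances. Deliberately naive: exhaustive
# enumeration only, no shared code with the package internals.

# all k-permutations of x, as a list
perms_of <- function(x, k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perms_of(x[-i], k - 1L)) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

# every embedding of `motif` in `network` by exhaustive injective node
# mapping, collapsed to sorted edge-index sets
brute_embeddings <- function(network, motif) {
  ekey <- paste(network$edges$source, network$edges$target, sep = "\r")
  mn <- motif$nodes
  found <- character(0)
  res <- list()
  for (mp in perms_of(network$nodes, length(mn))) {
    names(mp) <- mn
    idx <- match(paste(mp[motif$edges$source], mp[motif$edges$target],
                       sep = "\r"), ekey)
    if (anyNA(idx)) next
    key <- paste(sort(idx), collapse = ",")
    if (!key %in% found) {
      found <- c(found, key)
      res[[length(res) + 1L]] <- sort(idx)
    }
  }
  res
}

# raw count of injective node mappings (no edge-set collapse)
brute_mapping_count <- function(network, motif) {
  ekey <- paste(network$edges$source, network$edges$target, sep = "\r")
  mn <- motif$nodes
  n <- 0L
  for (mp in perms_of(network$nodes, length(mn))) {
    names(mp) <- mn
    idx <- match(paste(mp[motif$edges$source], mp[motif$edges$target],
                       sep = "\r"), ekey)
    if (!anyNA(idx)) n <- n + 1L
  }
  n
}

# true maximum feasible subset size by scanning all 2^n subsets;
# optionally forces a set of embedding positions into every subset
naive_max_feasible <- function(embeddings, capacity, force = integer(0)) {
  n <- length(embeddings)
  stopifnot(n <= 15L)
  best <- -1L
  for (mask in 0:(2^n - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (!all(force %in% sel)) next
    u <- integer(length(capacity))
    for (i in sel) u[embeddings[[i]]] <- u[embeddings[[i]]] + 1L
    if (all(u <= capacity) && length(sel) > best) best <- length(sel)
  }
  best
}

# does the edge-subgraph given by edge indices `h` realize the motif?
# exhaustive bijection check, independent of any matcher
edges_realize_motif <- function(network, h, motif) {
  sub <- network$edges[h, , drop = FALSE]
  nodes <- unique(c(sub$source, sub$target))
  if (length(nodes) != length(motif$nodes)) return(FALSE)
  if (nrow(sub) != nrow(motif$edges)) return(FALSE)
  skey <- sort(paste(sub$source, sub$target, sep = "\r"))
  for (mp in perms_of(nodes, length(motif$nodes))) {
    names(mp) <- motif$nodes
    if (identical(sort(paste(mp[motif$edges$source], mp[motif$edges$target],
                             sep = "\r")), skey)) {
      return(TRUE)
    }
  }
  FALSE
}

# random small directed network: n nodes, m arcs, capacities drawn 1..3
random_small_network <- function(seed, n = 8L, m = 14L, cap = NULL) {
  set.seed(seed)
  arcs <- expand.grid(s = seq_len(n), t = seq_len(n))
  arcs <- arcs[arcs$s != arcs$t, ]
  pick <- arcs[sample.int(nrow(arcs), min(m, nrow(arcs))), ]
  if (is.null(cap)) cap <- sample(1:3, nrow(pick), replace = TRUE)
  pomoc_network(data.frame(source = paste0("n", pick$s),
                           target = paste0("n", pick$t)),
                capacity = cap,
                nodes = paste0("n", seq_len(n)))
}

embedding_keys <- function(x) sort(vapply(x, paste, "", collapse = ","))
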