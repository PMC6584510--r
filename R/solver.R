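#' Solver configuration for the iterated local search
#'
#' @param p perturbation probability: each solution member independently
#'   undergoes a Bernoulli trial with probability `p` deciding whether a
#'   same-size replacement is attempted before the next improvement pass.
#' @param stall_limit number of consecutive outer iterations without an
#'   improvement of the best solution size after which the search stops.
#' @param max_iter safety cap on outer iterations.
#' @param seed integer seed making the whole run reproducible; when `NULL` a
#'   seed is drawn and recorded in the returned solution.
#' @return a list of class `pomoc_control`.
#' @export
pomoc_control <- function(p = 0.1, stall_limit = 20L, max_iter = 10000L,
                          seed = NULL) {
  stopifnot(p >= 0, p <= 1, stall_limit >= 1, max_iter >= 1)
  structure(list(p = p, stall_limit = as.integer(stall_limit),
                 max_iter = as.integer(max_iter), seed = seed),
            class = "pomoc_control")
}

# residual capacities left by a selection of overlap-graph vertices
og_residual <- function(overlap, capacity, selected) {
  capacity - usage_vector(overlap$embeddings[selected], length(capacity))
}

#' Grow a random maximal feasible selection on the overlap graph
#'
#' Repeatedly picks a uniformly random remaining vertex, adds its embedding
#' to the selection and decrements the capacities of its edges; whenever an
#' edge's remaining capacity drops to zero, every remaining embedding
#' containing that edge is discarded. Stops when no vertex remains, so the
#' result is maximal: no discarded embedding can be added back without
#' violating a capacity.
#'
#' Uses the current R random number generator; seed it for reproducibility.
#'
#' @param overlap a `pomoc_overlap` from [build_overlap_graph()].
#' @param capacity residual per-edge capacities available to these
#'   embeddings.
#' @return integer vector of selected overlap-graph vertex ids (sorted).
#' @export
random_feasible_extension <- function(overlap, capacity) {
  r <- capacity
  active <- which(vapply(overlap$embeddings, function(h) all(r[h] >= 1), NA))
  selected <- integer(0)
  while (length(active)) {
    v <- active[[sample.int(length(active), 1L)]]
    h <- overlap$embeddings[[v]]
    selected <- c(selected, v)
    r[h] <- r[h] - 1
    dead <- unique(unlist(overlap$incidence[h[r[h] == 0]], use.names = FALSE))
    active <- setdiff(active, c(v, dead))
  }
  sort(selected)
}

#' One local-search improvement pass (1-out/2-in swaps plus additions)
#'
#' Scans the current solution members in random order. For each member, all
#' pairs of its non-solution overlap-graph neighbors whose joint substitution
#' keeps the solution feasible are collected, and one such swap (removing the
#' member, inserting the pair) is applied uniformly at random; every applied
#' swap grows the solution by one. After the scan, any non-solution embedding
#' still addable without violating a capacity is added.
#'
#' @param selected integer vector of solution vertex ids.
#' @inheritParams random_feasible_extension
#' @return list with elements `selected` (new solution) and `improved`
#'   (logical: did the size grow?).
#' @export
local_search_pass <- function(selected, overlap, capacity) {
  emb <- overlap$embeddings
  r <- og_residual(overlap, capacity, selected)
  insol <- logical(overlap$n)
  insol[selected] <- TRUE
  size0 <- length(selected)
  scan <- if (length(selected)) sample(selected) else integer(0)
  for (i in scan) {
    hi <- emb[[i]]
    r_out <- r
    r_out[hi] <- r_out[hi] + 1          # tentatively remove i
    cand <- overlap$adj[[i]]
    cand <- cand[!insol[cand]]
    cand <- cand[vapply(cand, function(j) all(r_out[emb[[j]]] >= 1), NA)]
    if (length(cand) < 2L) next
    pairs <- list()
    for (a in seq_len(length(cand) - 1L)) {
      j <- cand[a]
      r_j <- r_out
      r_j[emb[[j]]] <- r_j[emb[[j]]] - 1
      for (b in seq((a + 1L), length(cand))) {
        k <- cand[b]
        if (all(r_j[emb[[k]]] >= 1)) pairs[[length(pairs) + 1L]] <- c(j, k)
      }
    }
    if (!length(pairs)) next
    pick <- pairs[[sample.int(length(pairs), 1L)]]
    insol[i] <- FALSE
    insol[pick] <- TRUE
    r <- r_out
    for (v in pick) r[emb[[v]]] <- r[emb[[v]]] - 1
  }
  # addition sweep: include whatever still fits
  rest <- which(!insol)
  if (length(rest) > 1L) rest <- sample(rest)
  for (j in rest) {
    hj <- emb[[j]]
    if (all(r[hj] >= 1)) {
      insol[j] <- TRUE
      r[hj] <- r[hj] - 1
    }
  }
  selected <- which(insol)
  list(selected = selected, improved = length(selected) > size0)
}

#' Perturb a solution by same-size feasible replacements
#'
#' Each solution member independently undergoes a Bernoulli trial with
#' probability `p`; when selected, the member is replaced by one of its valid
#' non-solution overlap-graph neighbors (those whose substitution keeps the
#' solution feasible), chosen uniformly at random. Members without a valid
#' neighbor are left in place, so the solution size never changes and
#' feasibility is preserved.
#'
#' @inheritParams local_search_pass
#' @param p per-member replacement probability in `[0, 1]`.
#' @return integer vector: the perturbed solution (sorted).
#' @export
perturb_solution <- function(selected, overlap, capacity, p) {
  if (p <= 0 || !length(selected)) return(sort(selected))
  emb <- overlap$embeddings
  r <- og_residual(overlap, capacity, selected)
  insol <- logical(overlap$n)
  insol[selected] <- TRUE
  for (i in sort(selected)) {
    if (stats::runif(1L) >= p) next
    hi <- emb[[i]]
    r_out <- r
    r_out[hi] <- r_out[hi] + 1
    cand <- overlap$adj[[i]]
    cand <- cand[!insol[cand]]
    cand <- cand[vapply(cand, function(j) all(r_out[emb[[j]]] >= 1), NA)]
    if (!length(cand)) next
    j <- cand[[sample.int(length(cand), 1L)]]
    insol[i] <- FALSE
    insol[j] <- TRUE
    r <- r_out
    r[emb[[j]]] <- r[emb[[j]]] - 1
  }
  which(insol)
}

#' Partially overlapping motif count
#'
#' Finds a largest feasible set of motif embeddings under per-edge
#' capacities: no edge may belong to more selected embeddings than its
#' capacity. The search proceeds in four steps: (1) enumerate all embeddings
#' (the F1 set); (2) fix the embeddings guaranteed to belong to an optimum
#' (every edge has capacity for all its embeddings) and decrement capacities
#' accordingly; (3) build the overlap graph of the remaining embeddings and
#' grow a random maximal feasible solution on it; (4) iterate perturbation
#' (same-size random replacements with per-member probability `p`) and
#' local-search passes (1-out/2-in swaps plus additions), tracking the best
#' solution, until its size has not improved for `stall_limit` consecutive
#' iterations.
#'
#' With all capacities unbounded the result is the F1 count; with all
#' capacities 1 it is the F2 (edge-disjoint) count, see [count_f2()]. The
#' heuristic carries no optimality guarantee; [max_feasible_exact()] provides
#' ground truth for small instances.
#'
#' @param network a [pomoc_network()]; its `capacity` vector is used unless
#'   `capacity` is supplied.
#' @param motif a [motif_pattern()] (or builtin name).
#' @param control a [pomoc_control()].
#' @param capacity optional per-edge capacity override (positive integers or
#'   `Inf`, recycled if length 1).
#' @param induced passed to [enumerate_embeddings()].
#' @return object of class `pomoc_solution`: a list with the selected
#'   `embeddings`, their number `size`, the per-edge `usage`, the `capacity`
#'   vector, the F1 count `f1`, the number of `guaranteed` embeddings, the
#'   `seed`, `iterations` run, convergence flag, and the input `network` and
#'   `motif` for downstream reporting.
#' @examples
#' fx <- fig2_instance()
#' sol <- pomoc(fx$network, fx$motif, pomoc_control(seed = 1))
#' sol$size
#' @export
pomoc <- function(network, motif, control = pomoc_control(), capacity = NULL,
                  induced = FALSE) {
  if (is.character(motif)) motif <- motif_pattern(motif)
  cap <- if (is.null(capacity)) network$capacity else capacity
  m <- nrow(network$edges)
  if (length(cap) == 1L) cap <- rep(as.numeric(cap), m)
  stopifnot(length(cap) == m)
  embeddings <- enumerate_embeddings(network, motif, induced = induced)
  seed <- control$seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  res <- with_seed(seed, solve_pomoc(embeddings, cap, control))
  build_solution(res, embeddings, cap, network, motif, control, seed,
                 measure = "pomoc")
}

# core of steps 2-4, run under a seeded RNG; embeddings = full F1 set
solve_pomoc <- function(embeddings, cap, control) {
  nall <- length(embeddings)
  guar <- guaranteed_embeddings(embeddings, cap)
  residual <- cap - usage_vector(embeddings[guar], length(cap))
  pool_ids <- setdiff(seq_len(nall), guar)
  # embeddings already cut off by the guaranteed set cannot be chosen
  pool_ids <- pool_ids[vapply(pool_ids,
                              function(i) all(residual[embeddings[[i]]] >= 1),
                              NA)]
  if (!length(pool_ids)) {
    return(list(chosen = guar, guaranteed = guar, iterations = 0L,
                converged = TRUE))
  }
  overlap <- build_overlap_graph(embeddings[pool_ids], m = length(cap))
  sel <- random_feasible_extension(overlap, residual)
  sel <- local_search_pass(sel, overlap, residual)$selected
  best <- sel
  stall <- 0L
  iter <- 0L
  while (stall < control$stall_limit && iter < control$max_iter) {
    iter <- iter + 1L
    sel <- perturb_solution(sel, overlap, residual, control$p)
    sel <- local_search_pass(sel, overlap, residual)$selected
    if (length(sel) > length(best)) {
      best <- sel
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
  }
  list(chosen = sort(c(guar, pool_ids[best])), guaranteed = guar,
       iterations = iter, converged = stall >= control$stall_limit)
}

build_solution <- function(res, embeddings, cap, network, motif, control,
                           seed, measure) {
  chosen <- embeddings[res$chosen]
  if (length(chosen)) chosen <- unique_embeddings(chosen)
  if (!res$converged) {
    warning("iteration cap reached before the stall limit; ",
            "the solution may be improvable")
  }
  structure(list(
    embeddings = chosen,
    size = length(chosen),
    usage = usage_vector(chosen, length(cap)),
    capacity = cap,
    f1 = length(embeddings),
    guaranteed = length(res$guaranteed),
    measure = measure,
    control = control,
    seed = seed,
    iterations = res$iterations,
    converged = res$converged,
    network = network,
    motif = motif
  ), class = "pomoc_solution")
}

#' F2 motif count (edge-disjoint embeddings)
#'
#' The F2 measure is the size of a largest set of pairwise edge-disjoint
#' embeddings; it is the capacity-1 special case of the partially
#' overlapping count and is computed by the same search with every edge
#' capacity forced to 1.
#'
#' @inheritParams pomoc
#' @return a `pomoc_solution` with `measure = "f2"`.
#' @export
count_f2 <- function(network, motif, control = pomoc_control(),
                     induced = FALSE) {
  sol <- pomoc(network, motif, control = control,
               capacity = rep(1, nrow(network$edges)), induced = induced)
  sol$measure <- "f2"
  sol
}

#' @export
print.pomoc_solution <- function(x, ...) {
  cat(sprintf("%s motif count: %d\n",
              switch(x$measure, pomoc = "Partially overlapping", f2 = "F2",
                     exact = "Exact partially overlapping", x$measure),
              x$size))
  cat(sprintf("  motif: %s; embeddings enumerated (F1): %d; guaranteed: %d\n",
              x$motif$name, x$f1, x$guaranteed))
  cat(sprintf("  seed: %s; outer iterations: %d\n",
              format(x$seed), x$iterations))
  invisible(x)
}

#' @export
summary.pomoc_solution <- function(object, ...) {
  u <- object$usage
  cap <- object$capacity
  finite <- is.finite(cap)
  gene <- per_gene_motif_counts(object, object$network)
  out <- list(
    size = object$size,
    f1 = object$f1,
    measure = object$measure,
    saturated_edges = sum(u[finite] == cap[finite]),
    finite_edges = sum(finite),
    mean_usage = mean(u),
    top_genes = sort(gene, decreasing = TRUE)[seq_len(min(5L, length(gene)))]
  )
  class(out) <- "summary.pomoc_solution"
  out
}

#' @export
print.summary.pomoc_solution <- function(x, ...) {
  cat(sprintf("Motif count (%s): %d of %d enumerated embeddings\n",
              x$measure, x$size, x$f1))
  cat(sprintf("  %d of %d capacity-bounded edges saturated; mean edge usage %.2f\n",
              x$saturated_edges, x$finite_edges, x$mean_usage))
  cat("  most motif-active nodes:\n")
  print(x$top_genes)
  invisible(x)
}

#' Plot per-edge usage against capacity
#'
#' Bar plot of the solution's edge usage with capacity marks; saturated edges
#' (usage equal to a finite capacity) are highlighted.
#'
#' @param x a `pomoc_solution`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.pomoc_solution <- function(x, ...) {
  u <- x$usage
  cap <- x$capacity
  sat <- is.finite(cap) & u == cap
  bp <- graphics::barplot(u, names.arg = paste0("e", seq_along(u)),
                          col = ifelse(sat, "firebrick", "grey70"),
                          ylab = "embeddings using edge",
                          xlab = "network edge",
                          ylim = c(0, max(u, cap[is.finite(cap)], 1)), ...)
  graphics::points(bp, ifelse(is.finite(cap), cap, NA), pch = 4, lwd = 2)
  graphics::legend("topright", bty = "n", pch = c(15, 15, 4),
                   col = c("grey70", "firebrick", "black"),
                   legend = c("usage", "saturated", "capacity"))
  invisible(x)
}
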