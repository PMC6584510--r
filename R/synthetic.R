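#' Generate a random directed capacity-annotated network
#'
#' Draws an undirected skeleton from one of three topology models, orients
#' every edge independently with a fair coin, and attaches capacities. The
#' defaults reproduce the synthetic evaluation conditions: average total
#' degree 6 (so roughly `3n` edges) and all capacities fixed at 2.
#'
#' * `"er"`: Erdos-Renyi `G(n, m)` with exactly `n * avg_degree / 2` edges;
#' * `"ws"`: Watts-Strogatz small-world ring lattice with
#'   `avg_degree / 2` neighbors per side and rewiring probability `ws_p`
#'   (default 0.1, the canonical small-world regime);
#' * `"ba"`: Barabasi-Albert preferential attachment adding
#'   `avg_degree / 2` edges per vertex.
#'
#' @param model `"er"`, `"ws"` or `"ba"`.
#' @param n number of nodes.
#' @param avg_degree target average total (in + out) degree; default 6.
#' @param capacity capacity scheme: `"fixed:k"` sets every edge to `k`;
#'   `"uniform:lo:hi"` draws each capacity uniformly from the integers
#'   `lo..hi` (the random scheme of the evaluation is `"uniform:1:3"`);
#'   `"inf"` leaves all edges unbounded.
#' @param ws_p Watts-Strogatz rewiring probability.
#' @param seed integer seed; identical seeds give identical networks.
#' @return a valid [pomoc_network()] with nodes `v1..vn`.
#' @examples
#' net <- generate_network("er", n = 50, seed = 1)
#' nrow(net$edges)  # 150 = 50 * 6 / 2
#' @export
generate_network <- function(model = c("er", "ws", "ba"), n,
                             avg_degree = 6, capacity = "fixed:2",
                             ws_p = 0.1, seed = NULL) {
  model <- match.arg(model)
  half <- avg_degree / 2
  build <- function() {
    g <- switch(model,
      er = igraph::sample_gnm(n, round(n * half), directed = FALSE),
      ws = igraph::sample_smallworld(1, n, round(half), ws_p),
      ba = igraph::sample_pa(n, m = round(half), directed = FALSE))
    g <- igraph::simplify(g)
    el <- igraph::as_edgelist(g, names = FALSE)
    flip <- stats::runif(nrow(el)) < 0.5
    el[flip, ] <- el[flip, 2:1, drop = FALSE]
    m <- nrow(el)
    cap <- parse_capacity_scheme(capacity, m)
    pomoc_network(data.frame(source = paste0("v", el[, 1L]),
                             target = paste0("v", el[, 2L])),
                  capacity = cap,
                  nodes = paste0("v", seq_len(n)))
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

parse_capacity_scheme <- function(scheme, m) {
  if (is.numeric(scheme)) return(rep(as.numeric(scheme), length.out = m))
  parts <- strsplit(scheme, ":", fixed = TRUE)[[1L]]
  switch(parts[1L],
    fixed = {
      k <- as.numeric(parts[2L])
      if (!is.finite(k) || k < 1) stop("fixed capacity must be >= 1")
      rep(k, m)
    },
    uniform = {
      lo <- as.integer(parts[2L]); hi <- as.integer(parts[3L])
      if (is.na(lo) || is.na(hi) || lo < 1 || hi < lo) {
        stop("uniform capacity scheme needs 1 <= lo <= hi")
      }
      as.numeric(sample(seq(lo, hi), m, replace = TRUE))
    },
    inf = rep(Inf, m),
    stop("unknown capacity scheme '", scheme,
         "'; use 'fixed:k', 'uniform:lo:hi' or 'inf'")
  )
}

#' Benchmark motif counts over synthetic networks
#'
#' For every combination of model, size, capacity scheme and motif, generates
#' `replicates` networks and reports the mean and twice the standard error of
#' the F1, F2 and partially overlapping counts, plus (non-normative) wall
#' time. The sandwich F2 <= POMOC <= F1 holds row by row.
#'
#' @param models subset of `c("er", "ws", "ba")`.
#' @param sizes node counts.
#' @param schemes capacity scheme strings (see [generate_network()]).
#' @param motifs motif names or [motif_pattern()] objects.
#' @param replicates networks per cell.
#' @param seed base seed; replicate `r` of each cell derives its own seed.
#' @param avg_degree average total degree of the generated networks.
#' @param control solver settings for the POMOC and F2 runs.
#' @return data frame with one row per cell.
#' @export
run_benchmark <- function(models = c("er", "ws", "ba"), sizes = c(200L, 400L),
                          schemes = "fixed:2", motifs = c("bifan", "biparallel",
                                                          "cascade", "feed_forward"),
                          replicates = 10L, seed = 1L, avg_degree = 6,
                          control = pomoc_control()) {
  if (is.character(motifs)) motifs <- lapply(motifs, motif_pattern)
  rows <- list()
  cell <- 0L
  for (model in models) for (n in sizes) for (scheme in schemes) {
    cell <- cell + 1L
    nets <- lapply(seq_len(replicates), function(r) {
      generate_network(model, n, avg_degree = avg_degree, capacity = scheme,
                       seed = seed + 7919L * cell + r)
    })
    for (motif in motifs) {
      f1 <- f2 <- po <- tm <- numeric(replicates)
      for (r in seq_len(replicates)) {
        ctl <- control
        ctl$seed <- seed + 104729L * cell + r
        t0 <- proc.time()[["elapsed"]]
        sol <- pomoc(nets[[r]], motif, control = ctl)
        tm[r] <- proc.time()[["elapsed"]] - t0
        f1[r] <- sol$f1
        po[r] <- sol$size
        f2[r] <- count_f2(nets[[r]], motif, control = ctl)$size
      }
      se2 <- function(x) if (length(x) > 1L) 2 * stats::sd(x) / sqrt(length(x)) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        model = model, n = n, scheme = scheme, motif = motif$name,
        replicates = replicates,
        f1_mean = mean(f1), f1_se2 = se2(f1),
        f2_mean = mean(f2), f2_se2 = se2(f2),
        pomoc_mean = mean(po), pomoc_se2 = se2(po),
        time_s = mean(tm))
    }
  }
  do.call(rbind, rows)
}
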