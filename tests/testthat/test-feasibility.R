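fx <- fig2_instance()
H <- fx$embeddings
CAP <- fx$network$capacity

test_that("usage vectors match the worked example", {
  expect_identical(usage_vector(H[c("H1", "H6")], 8L),
                   c(1L, 1L, 1L, 0L, 0L, 1L, 1L, 1L))
  expect_identical(usage_vector(H[c("H2", "H5", "H6")], 8L),
                   c(1L, 1L, 0L, 2L, 1L, 2L, 1L, 1L))
  expect_identical(usage_vector(list(), 8L), integer(8))
})

test_that("usage entries always sum to motif size times subset size", {
  for (seed in 1:10) {
    set.seed(seed)
    sub <- H[sample(6, sample(0:6, 1))]
    expect_identical(sum(usage_vector(sub, 8L)), 3L * length(sub))
  }
})

test_that("feasibility follows the capacity constraints", {
  expect_true(is_feasible(H[c("H1", "H6")], CAP))
  expect_false(is_feasible(H[c("H1", "H2")], CAP))
  expect_true(is_feasible(list(), CAP))
  expect_true(is_feasible(H, rep(Inf, 8)))  # unbounded sentinel
})

test_that("feasibility is downward closed", {
  for (seed in 1:20) {
    set.seed(seed)
    net <- random_small_network(seed, n = 7L, m = 12L)
    embs <- enumerate_embeddings(net, motif_pattern("cascade"))
    if (length(embs) < 2) next
    sub <- embs[sample(length(embs), min(4L, length(embs)))]
    if (is_feasible(sub, net$capacity)) {
      for (drop in seq_along(sub)) {
        expect_true(is_feasible(sub[-drop], net$capacity))
      }
    }
  }
})

test_that("guaranteed embeddings are exactly those with fully covered edges", {
  expect_identical(names(H)[guaranteed_embeddings(unname(H), CAP)], "H6")
  expect_identical(guaranteed_embeddings(unname(H), rep(Inf, 8)), 1:6)
  # with all capacities 1, guaranteed = embeddings sharing no edge with others
  for (seed in 1:15) {
    net <- random_small_network(seed, n = 7L, m = 12L)
    embs <- enumerate_embeddings(net, motif_pattern("cascade"))
    if (!length(embs)) next
    got <- guaranteed_embeddings(embs, rep(1, 12))
    lonely <- which(vapply(seq_along(embs), function(i) {
      others <- unlist(embs[-i])
      !any(embs[[i]] %in% others)
    }, NA))
    expect_identical(got, lonely, info = paste("seed", seed))
  }
})

test_that("fixing a guaranteed embedding never costs optimality", {
  for (seed in 1:20) {
    net <- random_small_network(seed, n = 7L, m = 12L)
    embs <- enumerate_embeddings(net, motif_pattern("feed_forward"))
    if (!length(embs) || length(embs) > 12) next
    guar <- guaranteed_embeddings(embs, net$capacity)
    free_opt <- naive_max_feasible(embs, net$capacity)
    forced_opt <- naive_max_feasible(embs, net$capacity, force = guar)
    expect_identical(forced_opt, free_opt, info = paste("seed", seed))
  }
})

test_that("the overlap graph records pairwise edge sharing", {
  pool <- H[c("H1", "H2", "H3", "H4", "H5")]  # the non-guaranteed five
  og <- build_overlap_graph(unname(pool), m = 8L)
  expect_identical(og$n, 5L)
  # symmetry and degree = number of other embeddings sharing an edge
  for (i in seq_len(og$n)) {
    for (j in og$adj[[i]]) expect_true(i %in% og$adj[[j]])
    sharing <- sum(vapply(seq_len(og$n), function(j) {
      j != i && length(intersect(pool[[i]], pool[[j]])) > 0
    }, NA))
    expect_identical(length(og$adj[[i]]), sharing)
  }
  # idempotence
  og2 <- build_overlap_graph(unname(pool), m = 8L)
  expect_identical(og$adj, og2$adj)

  disjoint <- build_overlap_graph(list(c(1L, 2L), c(3L, 4L)), m = 4L)
  expect_identical(lengths(disjoint$adj), c(0L, 0L))
  touching <- build_overlap_graph(list(c(1L, 2L), c(2L, 3L)), m = 3L)
  expect_identical(touching$adj, list(2L, 1L))
})

test_that("per-node motif counts recount embedding membership", {
  expect_identical(sum(per_gene_motif_counts(list(), fx$network)), 0L)
  one <- per_gene_motif_counts(H["H6"], fx$network)  # e2,e7,e8: v5,v3,v6,v2
  expect_identical(sort(names(one)[one == 1L]), sort(c("v5", "v3", "v6", "v2")))
  expect_identical(sum(one), 4L)
  sol <- H[c("H1", "H4", "H5", "H6")]
  counts <- per_gene_motif_counts(sol, fx$network)
  src <- fx$network$edges$source
  tgt <- fx$network$edges$target
  for (v in fx$network$nodes) {
    manual <- sum(vapply(sol, function(h) v %in% c(src[h], tgt[h]), NA))
    expect_identical(counts[[v]], manual)
  }
})
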