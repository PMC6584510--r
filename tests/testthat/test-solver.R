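fx <- fig2_instance()
H <- fx$embeddings
CAP <- fx$network$capacity

# the residual instance after fixing the guaranteed embedding H6
pool <- unname(H[c("H1", "H2", "H3", "H4", "H5")])
residual <- CAP - usage_vector(H["H6"], 8L)
og_pool <- build_overlap_graph(pool, m = 8L)

test_that("random maximal extension is feasible and maximal", {
  sizes <- integer(0)
  for (seed in 1:200) {
    set.seed(seed)
    sel <- random_feasible_extension(og_pool, residual)
    expect_true(is_feasible(pool[sel], residual))
    # maximal: nothing else can be added
    r <- residual - usage_vector(pool[sel], 8L)
    for (j in setdiff(seq_along(pool), sel)) {
      expect_false(all(r[pool[[j]]] >= 1))
    }
    sizes <- c(sizes, length(sel))
  }
  expect_setequal(unique(sizes), c(2L, 3L))

  # no conflicts: everything is selected
  disjoint <- build_overlap_graph(list(c(1L, 2L), c(3L, 4L)), m = 4L)
  set.seed(1)
  expect_identical(random_feasible_extension(disjoint, rep(5, 4)), c(1L, 2L))
  empty <- build_overlap_graph(list(), m = 4L)
  expect_identical(random_feasible_extension(empty, rep(5, 4)), integer(0))
})

test_that("a local search pass grows suboptimal solutions by 1-out/2-in swaps", {
  # {H2, H5} with H6 fixed corresponds to the size-3 solution of the text;
  # a swap must lift the residual solution to the residual optimum of 3
  start <- match(list(H$H2, H$H5), pool)
  set.seed(11)
  res <- local_search_pass(start, og_pool, residual)
  expect_true(res$improved)
  expect_identical(length(res$selected), 3L)
  expect_true(is_feasible(pool[res$selected], residual))

  # the optimum {H1, H4, H5} cannot be improved
  opt <- match(list(H$H1, H$H4, H$H5), pool)
  set.seed(12)
  res2 <- local_search_pass(opt, og_pool, residual)
  expect_false(res2$improved)
  expect_identical(length(res2$selected), 3L)

  # the addition sweep fills an empty solution
  set.seed(13)
  res3 <- local_search_pass(integer(0), og_pool, residual)
  expect_true(res3$improved)
  expect_gte(length(res3$selected), 2L)
})

test_that("perturbation preserves size and feasibility", {
  start <- match(list(H$H1, H$H4, H$H5), pool)
  set.seed(5)
  expect_identical(perturb_solution(start, og_pool, residual, p = 0),
                   sort(start))
  for (seed in 1:200) {
    set.seed(seed)
    out <- perturb_solution(start, og_pool, residual, p = 1)
    expect_identical(length(out), 3L)
    expect_true(is_feasible(pool[out], residual))
  }
  # pairwise-disjoint embeddings have no neighbors, hence no valid move
  disjoint <- build_overlap_graph(list(c(1L, 2L), c(3L, 4L)), m = 4L)
  set.seed(1)
  expect_identical(perturb_solution(c(1L, 2L), disjoint, rep(1, 4), p = 1),
                   c(1L, 2L))
})

test_that("the full search solves the worked example", {
  sol <- pomoc(fx$network, fx$motif, pomoc_control(seed = 42))
  expect_identical(sol$size, 4L)
  expect_true(is_feasible(sol$embeddings, CAP))
  # the guaranteed embedding is always part of the solution
  expect_true(paste(H$H6, collapse = ",") %in%
                vapply(sol$embeddings, paste, "", collapse = ","))
  # capacity special cases
  expect_identical(count_f2(fx$network, fx$motif, pomoc_control(seed = 1))$size,
                   2L)
  unbounded <- pomoc(fx$network, fx$motif, pomoc_control(seed = 1),
                     capacity = Inf)
  expect_identical(unbounded$size, 6L)
  expect_identical(unbounded$size, count_f1(fx$network, fx$motif))
})

test_that("identical seeds reproduce identical solutions", {
  net <- random_small_network(99, n = 10L, m = 25L)
  a <- pomoc(net, "feed_forward", pomoc_control(seed = 123))
  b <- pomoc(net, "feed_forward", pomoc_control(seed = 123))
  expect_identical(a$embeddings, b$embeddings)
  expect_identical(a$size, b$size)
  expect_identical(a$iterations, b$iterations)
})

test_that("solutions are feasible, contain the guaranteed set, and respect the sandwich", {
  for (seed in 1:10) {
    net <- random_small_network(seed, n = 9L, m = 18L)
    for (motif in c("cascade", "feed_forward")) {
      ctl <- pomoc_control(seed = seed)
      sol <- pomoc(net, motif, ctl)
      expect_true(is_feasible(sol$embeddings, net$capacity))
      f2 <- count_f2(net, motif, ctl)$size
      expect_lte(f2, sol$size)
      expect_lte(sol$size, sol$f1)
      embs <- enumerate_embeddings(net, motif_pattern(motif))
      guar <- embs[guaranteed_embeddings(embs, net$capacity)]
      keys <- vapply(sol$embeddings, paste, "", collapse = ",")
      for (g in guar) expect_true(paste(g, collapse = ",") %in% keys)
    }
  }
})

test_that("solution objects print, summarize and serialize", {
  sol <- pomoc(fx$network, fx$motif, pomoc_control(seed = 7))
  expect_output(print(sol), "count: 4")
  s <- summary(sol)
  expect_identical(s$size, 4L)
  expect_output(print(s), "enumerated embeddings")
  counts <- per_gene_motif_counts(sol, fx$network)
  expect_identical(length(counts), 8L)
})
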