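test_that("ER networks hit the exact edge count implied by the average degree", {
  net <- generate_network("er", n = 200, avg_degree = 6, seed = 1)
  expect_identical(nrow(net$edges), 600L)
  expect_length(validate_network(net), 0)
  expect_true(all(net$capacity == 2))  # default scheme fixed:2
})

test_that("capacity schemes are honored", {
  net <- generate_network("er", n = 100, capacity = "fixed:3", seed = 2)
  expect_true(all(net$capacity == 3))
  net <- generate_network("er", n = 100, capacity = "uniform:1:3", seed = 2)
  expect_true(all(net$capacity %in% 1:3))
  expect_setequal(unique(net$capacity), c(1, 2, 3))
  net <- generate_network("er", n = 50, capacity = "inf", seed = 2)
  expect_true(all(is.infinite(net$capacity)))
  expect_error(generate_network("er", 50, capacity = "fixed:0", seed = 1), ">= 1")
  expect_error(generate_network("er", 50, capacity = "banana", seed = 1),
               "unknown capacity scheme")
})

test_that("all models produce valid networks near the target degree", {
  for (model in c("er", "ws", "ba")) {
    net <- generate_network(model, n = 200, avg_degree = 6, seed = 11)
    expect_length(validate_network(net), 0)
    mean_deg <- 2 * nrow(net$edges) / length(net$nodes)
    expect_gt(mean_deg, 6 * 0.9)
    expect_lt(mean_deg, 6 * 1.1)
  }
})

test_that("generation is deterministic per seed", {
  for (model in c("er", "ws", "ba")) {
    a <- generate_network(model, n = 100, seed = 7)
    b <- generate_network(model, n = 100, seed = 7)
    expect_identical(a, b)
    c <- generate_network(model, n = 100, seed = 8)
    expect_false(identical(a$edges, c$edges))
  }
})

test_that("edge orientation is a fair coin", {
  # gnm skeletons store pairs low->high; orientation flips half of them
  net <- generate_network("er", n = 2000, avg_degree = 6, seed = 3)
  ids <- function(x) as.integer(sub("^v", "", x))
  forward <- sum(ids(net$edges$source) < ids(net$edges$target))
  p <- stats::binom.test(forward, nrow(net$edges), 0.5)$p.value
  expect_gt(p, 1e-6)
})

test_that("benchmark rows respect the count sandwich", {
  bench <- run_benchmark(models = c("er", "ba"), sizes = 60L,
                         schemes = "fixed:2",
                         motifs = c("cascade", "feed_forward"),
                         replicates = 2L, seed = 5,
                         control = pomoc_control(stall_limit = 5L))
  expect_identical(nrow(bench), 4L)
  expect_true(all(bench$f2_mean <= bench$pomoc_mean + 1e-9))
  expect_true(all(bench$pomoc_mean <= bench$f1_mean + 1e-9))
})
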