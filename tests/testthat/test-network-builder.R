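test_that("builds are deterministic given a seed and refuse without one", {
  np <- network_params("reduced", n_hc = 2, grid = c(2, 1), mc_per_hc = 4,
                       pyr_per_mc = 6, bask_per_mc = 2, n_items = 4)
  a <- build_network(np, seed = 3)
  b <- build_network(np, seed = 3)
  expect_identical(a$conns, b$conns)
  expect_identical(a$cells, b$cells)
  c2 <- build_network(np, seed = 4)
  expect_false(identical(a$conns, c2$conns))
  expect_error(build_network(np), "seed")
})

test_that("population totals and connection counts match binomial expectations", {
  np <- network_params("full")
  stopifnot(np$n_hc == 9, np$mc_per_hc == 16)
  # totals from the layout arithmetic (no build needed at full scale)
  expect_equal(2 * np$n_hc * np$mc_per_hc * np$pyr_per_mc, 8640)
  expect_equal(2 * np$n_hc * np$mc_per_hc * np$bask_per_mc, 1152)

  npr <- network_params("reduced")
  net <- build_network(npr, seed = 13)
  n_pyr <- npr$n_hc * npr$mc_per_hc * npr$pyr_per_mc  # per network
  # associative connections: cp_ppa * n_pyr^2 * 2 directions
  n_assoc <- sum(net$conns$type == 1L)
  exp_assoc <- npr$cp_ppa * n_pyr^2 * 2
  sd_assoc <- sqrt(exp_assoc * (1 - npr$cp_ppa))
  expect_lt(abs(n_assoc - exp_assoc), 4 * sd_assoc)
  # within-network: cp over ordered pyr pairs of each network
  n_within <- sum(net$conns$type == 0L)
  exp_within <- 2 * npr$cp_pp * n_pyr * (n_pyr - 1)
  expect_lt(abs(n_within - exp_within),
            4 * sqrt(exp_within * (1 - npr$cp_pp)))
})

test_that("basket connectivity is confined to the local hypercolumn", {
  net <- tiny_network()
  cl <- net$cells
  pb <- net$conns[net$conns$type %in% c(2L, 3L), ]
  key <- function(ids) paste(cl$network[ids + 1], cl$hc[ids + 1])
  expect_true(all(key(pb$pre) == key(pb$post)))
})

test_that("memory patterns claim one minicolumn per hypercolumn without overlap", {
  net <- tiny_network()
  for (g in 1:2) {
    claimed <- do.call(rbind, net$patterns[[g]])
    expect_false(anyDuplicated(claimed) > 0)
    for (pat in net$patterns[[g]])
      expect_equal(sort(pat$hc), seq_len(net$params$n_hc))
  }
})

test_that("conduction delay sampling follows the distance rule", {
  set.seed(17)
  # zero distance: mean equals the minimal synaptic delay (the 30% SD
  # still applies; samples are clamped below at the minimum)
  d0 <- sample_delay(rep(0, 20000), speed = 2)
  expect_true(all(d0 >= 1.5))
  expect_equal(mean(d0), 1.5 + 0.3 * 1.5 / sqrt(2 * pi), tolerance = 0.01)
  # between networks: 10 mm at 2 m/s -> mean 6.5 ms
  d1 <- sample_delay(rep(10, 20000), speed = 2)
  expect_equal(mean(d1), 6.5, tolerance = 0.02)
  # within network: 0.5 mm at 0.2 m/s -> mean 4.0 ms, relative SD 30%
  d2 <- sample_delay(rep(0.5, 20000), speed = 0.2)
  expect_equal(mean(d2), 4.0, tolerance = 0.02)
  expect_equal(sd(d2), 1.2, tolerance = 0.05)
  expect_true(all(d2 >= 1.5))
})

test_that("preloading is reproducible and produces the attractor weight structure", {
  net <- tiny_network()
  w <- weight_class_summary(net)
  expect_gt(w[["same_pattern_within_hc"]], w[["same_pattern_across_hc"]])
  expect_gt(w[["same_pattern_across_hc"]], 0)
  expect_lt(w[["different_pattern"]], 0)
  # reproducibility: same seed, same weights
  np <- net$params
  net2 <- build_network(np, seed = 7)
  net2 <- preload_attractors(net2, preload_params(n_cycles = 4),
                             bcpnn_params(), seed = 8)
  expect_equal(net$conns$w_ampa, net2$conns$w_ampa, tolerance = 1e-12)
  expect_error(preload_attractors(net2, preload_params(), bcpnn_params()),
               "seed")
})

test_that("preloaded within-HC connections give EPSPs in the reported range", {
  # full-scale parameters on a single-hypercolumn fragment: the within-HC
  # population is HC-local, so one HC suffices to measure it
  np <- network_params("full", n_hc = 1, grid = c(1, 1))
  net <- build_network(np, seed = 19)
  cl <- net$cells; co <- net$conns
  keep <- co$type != 0L | (cl$pattern[co$pre + 1] == cl$pattern[co$post + 1])
  net$conns <- co[keep, ]
  net <- preload_attractors(net, preload_params(), bcpnn_params(), seed = 20)
  psp <- measure_psp_sample(net, "within_hc", n_sample = 60)
  expect_gt(mean(psp), 0.72 - 0.085)
  expect_lt(mean(psp), 0.72 + 0.085)
})
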