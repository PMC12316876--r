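make_cfg <- function(net, ...) {
  experiment_config(scale = "reduced", seed = 1, network = net$params, ...)
}

test_that("with all synapses and noise silenced every neuron relaxes to the leak reversal", {
  net <- tiny_network()
  cfg <- make_cfg(net)
  cfg$stim$r_bg <- 0
  # suppress the intrinsic-excitability current to isolate the leak
  cfg$bcpnn$beta_gain <- 0
  eng <- create_engine(net, cfg)
  set.seed(1)
  .e <- bcpnnet:::.cpp_engine_advance(eng, 500)
  V <- bcpnnet:::.cpp_engine_voltages(eng)
  # the exponential upstroke tail leaves the rest point ~0.02 mV above
  # the leak reversal
  expect_true(all(abs(V - cfg$neuron$E_L) < 0.05))
})

test_that("identical network, schedule and seeds give bit-identical spike records", {
  net <- tiny_network()
  cfg <- make_cfg(net, record_spikes = TRUE)
  sched <- generate_schedule("exp1_arr1", seed = 42, n_items = 8)
  s1 <- run_session(net, sched, cfg, noise_seed = 5)
  s2 <- run_session(net, sched, cfg, noise_seed = 5)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$trials, s2$trials)
  s3 <- run_session(net, sched, cfg, noise_seed = 6)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("spike records respect the refractory period per neuron", {
  net <- tiny_network()
  cfg <- make_cfg(net, record_spikes = TRUE)
  sched <- generate_schedule("exp1_arr1", seed = 43, n_items = 8)
  s <- run_session(net, sched, cfg, noise_seed = 7)
  sp <- s$spikes[order(s$spikes$gid, s$spikes$time_ms), ]
  gaps <- unlist(tapply(sp$time_ms, sp$gid, diff))
  expect_gt(nrow(sp), 100)
  expect_true(all(gaps >= cfg$neuron$tau_ref - 1e-9))
})

test_that("frozen within-network weights are identical before and after a session", {
  net <- tiny_network()
  cfg <- make_cfg(net)
  sched <- generate_schedule("exp1_arr1", seed = 44, n_items = 8)
  s <- run_session(net, sched, cfg, noise_seed = 8)
  expect_identical(s$within_weights_start, s$within_weights_end)
})

test_that("snapshots are complete and stable under frozen plasticity", {
  net <- tiny_network()
  cfg <- make_cfg(net)
  eng <- create_engine(net, cfg)
  snap <- snapshot_state(eng)
  expect_equal(nrow(snap$assoc), sum(net$conns$type == 1L))
  # associative weights start at zero (traces initialized independent)
  expect_lt(max(abs(snap$assoc$w_ampa)), 1e-9)
  expect_lt(max(abs(snap$assoc$w_nmda)), 1e-9)
  # silence with kappa = 0: probability traces identical across snapshots
  bcpnnet:::.cpp_engine_set_kappa(eng, 0)
  cfg2 <- cfg; cfg2$stim$r_bg <- 0
  set.seed(2)
  bcpnnet:::.cpp_engine_advance(eng, 200)
  snap2 <- snapshot_state(eng)
  expect_identical(snap$assoc$P_ij_ampa, snap2$assoc$P_ij_ampa)
  expect_identical(snap$assoc$P_i_nmda, snap2$assoc$P_i_nmda)
})

test_that("severing disynaptic inhibition removes exactly the negative associative weights", {
  net <- tiny_network()
  cfg <- make_cfg(net)
  sched <- generate_schedule("exp1_arr1", seed = 45, n_items = 8)
  eng <- create_engine(net, cfg)
  set.seed(3)
  # drive a few trials so associative weights differentiate
  ctx <- pattern_cells(net, 1, 2)
  it <- pattern_cells(net, 1, 1)
  bcpnnet:::.cpp_engine_set_stim(eng, c(ctx, it))
  bcpnnet:::.cpp_engine_advance(eng, 1500)
  bcpnnet:::.cpp_engine_set_stim(eng, ctx)
  bcpnnet:::.cpp_engine_advance(eng, 3000)
  before <- snapshot_state(eng)$assoc
  n_sev <- ablate(eng)
  after <- snapshot_state(eng)$assoc
  expect_gt(n_sev, 0)
  keep <- after$severed == 0
  expect_true(all(before$w_ampa[keep] >= 0 & before$w_nmda[keep] >= 0))
  # severed connections are exactly those with a negative component
  expect_equal(n_sev, sum(before$w_ampa < 0 | before$w_nmda < 0))
  expect_error(ablate(eng, "unknown_key"), "unknown ablation")
})

test_that("background-only activity stays near baseline without attractor flips", {
  net <- tiny_network()
  cfg <- make_cfg(net, record_spikes = TRUE)
  eng <- create_engine(net, cfg)
  set.seed(4)
  bcpnnet:::.cpp_engine_record(eng, TRUE)
  bcpnnet:::.cpp_engine_counts_reset(eng)
  bcpnnet:::.cpp_engine_advance(eng, 3000)
  cnt <- bcpnnet:::.cpp_engine_counts(eng)
  pyr <- net$cells$is_pyr
  expect_lt(mean(cnt[pyr]) / 3, 5)  # mean pyramidal rate below 5 Hz
  # no assembly ignites: per-assembly rates all stay low
  for (k in seq_len(net$params$n_items)) {
    cells <- pattern_cells(net, k, 1)
    expect_lt(mean(cnt[cells + 1]) / 3, 10)
  }
})

test_that("cueing an item ignites its assembly and suppresses competitors", {
  net <- tiny_network()
  cfg <- make_cfg(net)
  eng <- create_engine(net, cfg)
  set.seed(5)
  bcpnnet:::.cpp_engine_advance(eng, 500)
  it1 <- pattern_cells(net, 1, 1)
  it2 <- pattern_cells(net, 2, 1)
  bcpnnet:::.cpp_engine_set_stim(eng, it1)
  bcpnnet:::.cpp_engine_counts_reset(eng)
  bcpnnet:::.cpp_engine_advance(eng, 750)
  cnt <- bcpnnet:::.cpp_engine_counts(eng)
  f1 <- mean(cnt[it1 + 1]) / 0.25
  f2 <- mean(cnt[it2 + 1]) / 0.25
  expect_gt(f1, 5)
  expect_lt(f2, f1 / 3)
})
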