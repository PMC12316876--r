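test_that("first spike from rest follows the stated jump ordering", {
  p <- stp_params()  # U = 0.2
  res <- stp_on_spike(stp_state(p), p, t_spike = 0)
  expect_equal(res$state$u, 0.36)
  expect_equal(res$release_gain, 0.36)
  expect_equal(res$state$x, 0.64)
})

test_that("state relaxes to (U, 1) after prolonged silence", {
  p <- stp_params()
  res <- stp_on_spike(stp_state(p), p, 0)
  st <- res$state
  # relax over many augmentation time constants, then probe with a spike
  res2 <- stp_on_spike(st, p, 100 * p$tau_A)
  expect_equal(res2$release_gain, 0.36, tolerance = 1e-10)
})

test_that("u and x stay within [0, 1] for arbitrary spike trains", {
  p <- stp_params()
  set.seed(5)
  for (rep in 1:20) {
    times <- sort(runif(200, 0, 5000))
    tr <- stp_train(times, p)
    expect_true(all(tr$u >= 0 & tr$u <= 1))
    expect_true(all(tr$x >= 0 & tr$x <= 1))
  }
})

test_that("periodic trains converge to the event-oracle fixed point", {
  p <- stp_params()
  times <- seq(20, by = 20, length.out = 1000)
  tr <- stp_train(times, p)
  g_oracle <- stp_event_oracle(times, p)
  expect_equal(tr$release_gain, g_oracle, tolerance = 1e-12)
  # periodic fixed point: consecutive late gains identical
  expect_equal(tr$release_gain[999], tr$release_gain[1000],
               tolerance = 1e-6)
})

test_that("event-driven update matches dense ODE integration on random trains", {
  p <- stp_params()
  set.seed(11)
  # random trains honoring the refractory period (no sub-5-ms gaps),
  # quantized to the oracle grid
  times <- round(cumsum(5 + rexp(60, 1 / 20)), 2)
  tr <- stp_train(times, p)
  dense <- stp_dense_oracle(times, p, t_end = max(times) + 1, dt = 0.01)
  expect_lt(max(abs(tr$u - dense$u)), 0.001)
  expect_lt(max(abs(tr$x - dense$x)), 0.001)
  rel <- abs(tr$release_gain - dense$release_gain) / dense$release_gain
  expect_lt(max(rel), 0.001)
})

test_that("conductance routing follows the weight sign", {
  g0 <- list(ampa = 0, nmda = 0, gaba = 0)
  g <- conductance_on_spike(g0, w_eff = 0.33, release_gain = 0.36)
  expect_equal(g$ampa, 0.1188)
  expect_equal(g$gaba, 0)
  g <- conductance_on_spike(g0, w_eff = -0.5, release_gain = 0.4)
  expect_equal(g$gaba, 0.2)
  expect_equal(g$ampa, 0)
  g <- conductance_on_spike(g0, w_eff = 0, release_gain = 0.9)
  expect_equal(unlist(g), unlist(g0))
  g <- conductance_on_spike(g0, w_eff = 0.1, release_gain = 1,
                            component = "nmda")
  expect_equal(g$nmda, 0.1)
})

test_that("closed-form PSP peak behaves at its trivial points", {
  expect_equal(psp_peak_closed_form(0, -75, -60, 5), 0)
  expect_equal(psp_peak_closed_form(7, -75, -75, 5), 0)
  ipsp <- psp_peak_closed_form(7, -75, -60, 5)
  expect_lt(abs(ipsp - (-1.18)), 0.02)
  # degenerate tau_m = tau_syn limit stays finite and continuous
  near <- psp_peak_closed_form(1, 0, -70, 19.999)
  at <- psp_peak_closed_form(1, 0, -70, 20)
  expect_lt(abs(near - at) / abs(at), 1e-3)
})

test_that("simulated single-synapse PSP agrees with the linear closed form", {
  p <- neuron_params()
  for (w in c(0.5, 1, 2)) {
    sim <- simulate_psp(w_ampa = w, release_gain = 1)
    oracle <- psp_peak_closed_form(w, 0, p$E_L, 5)
    expect_lt(abs(sim - oracle) / abs(oracle), 0.05)
  }
})
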