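test_that("leak equilibrium is a stable fixed point of the membrane update", {
  p <- neuron_params()
  st <- neuron_state(p)
  for (k in 1:5000) st <- step_membrane(st, p, dt = 0.1)
  # the exponential upstroke tail displaces the true rest point from E_L
  # by g_L Delta_T exp((E_L - V_t)/Delta_T) / g_L ~ 0.02 mV
  expect_lt(abs(st$V_m - p$E_L), 0.05)
  # and it stays there for arbitrarily long runs
  v1 <- st$V_m
  for (k in 1:5000) st <- step_membrane(st, p, dt = 0.1)
  expect_lt(abs(st$V_m - v1), 1e-9)
})

test_that("constant current drives the membrane to the leaky-integrator steady state", {
  p <- neuron_params()
  st <- neuron_state(p)
  # 100 pA: far from threshold, exponential term nearly negligible
  for (k in 1:20000) st <- step_membrane(st, p, I_ext = 100, dt = 0.1)
  expect_lt(abs(st$V_m - (p$E_L + 100 / p$g_L)), 0.25)
})

test_that("subthreshold step response relaxes with tau_m = C_m / g_L", {
  p <- neuron_params()
  I <- -50  # hyperpolarizing step: the exponential upstroke is negligible
  # empirical steady state under the drive
  st <- neuron_state(p)
  for (k in 1:4000) st <- step_membrane(st, p, I_ext = I, dt = 0.1)
  V_ss <- st$V_m
  # time constant from the decay of the gap between two time points
  st <- neuron_state(p)
  for (k in 1:100) st <- step_membrane(st, p, I_ext = I, dt = 0.1)
  g1 <- V_ss - st$V_m    # at 10 ms
  for (k in 1:200) st <- step_membrane(st, p, I_ext = I, dt = 0.1)
  g2 <- V_ss - st$V_m    # at 30 ms
  tau_est <- 20 / log(g1 / g2)
  expect_lt(abs(tau_est - p$C_m / p$g_L) / (p$C_m / p$g_L), 0.01)
})

test_that("spike emission resets, arms the refractory clock and increments adaptation", {
  p <- neuron_params()
  st <- neuron_state(p, V_m = -20)  # above the numerical cutoff
  res <- fire_and_reset(st, p)
  expect_true(res$spiked)
  expect_equal(res$state$V_m, p$V_r)
  expect_equal(res$state$I_w, p$b)
  expect_equal(res$state$refractory_remaining, p$tau_ref)
  # subthreshold: no spike, I_w decays with tau_Iw
  st2 <- res$state
  st2 <- step_membrane(st2, p, dt = 0.1)
  expect_equal(st2$I_w, p$b * exp(-0.1 / p$tau_Iw))
})

simulate_driven <- function(p, I_ext, t_max = 2000, dt = 0.1) {
  st <- neuron_state(p)
  spikes <- numeric(0)
  for (k in seq_len(t_max / dt)) {
    st <- step_membrane(st, p, I_ext = I_ext, dt = dt)
    r <- fire_and_reset(st, p)
    st <- r$state
    if (r$spiked) spikes <- c(spikes, k * dt)
  }
  spikes
}

test_that("no two spikes closer than the refractory period", {
  p <- neuron_params()
  sp <- simulate_driven(p, I_ext = 600, t_max = 1000)
  expect_gt(length(sp), 5)
  expect_true(all(diff(sp) >= p$tau_ref - 1e-9))
})

test_that("mean inter-spike interval grows monotonically with the adaptation increment", {
  isi <- vapply(c(0, 43, 86, 172), function(b) {
    sp <- simulate_driven(neuron_params(b = b), I_ext = 500, t_max = 3000)
    mean(diff(sp))
  }, numeric(1))
  expect_true(all(diff(isi) > 0))
})

test_that("simulated basket IPSP at -60 mV matches the printed amplitude and the closed form", {
  # single basket->pyramidal connection: 7 nS GABA transient at -60 mV
  sim <- simulate_psp(w_ampa = -7, V_hold = -60)
  oracle <- psp_peak_closed_form(7, E_syn = -75, V_hold = -60, tau_syn = 5)
  expect_lt(abs(sim - (-1.160)) / 1.160, 0.05)
  expect_lt(abs(sim - oracle) / abs(oracle), 0.05)
})

test_that("membrane integration flags numerical blow-up", {
  p <- neuron_params()
  st <- neuron_state(p)
  st$V_m <- NaN
  expect_error(step_membrane(st, p, dt = 0.1), "non-finite")
})
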