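test_that("weight and bias follow the log-probability forms", {
  tr <- bcpnn_traces(bcpnn_params(), P_i = 0.1, P_j = 0.1, P_ij = 0.05)
  expect_equal(compute_weight(tr, 0.33), 0.33 * log(5))
  tr0 <- bcpnn_traces(bcpnn_params(), P_i = 0.2, P_j = 0.3, P_ij = 0.06)
  expect_equal(compute_weight(tr0, 0.33), 0)  # independence
  trn <- bcpnn_traces(bcpnn_params(), P_i = 0.2, P_j = 0.3, P_ij = 0.01)
  expect_lt(compute_weight(trn, 0.33), 0)     # disynaptic inhibition
  expect_equal(compute_bias(1, 40), 0)
  expect_equal(compute_bias(0.0026, 40), 40 * log(0.0026))
  expect_equal(round(compute_bias(0.0026, 40), 1), -238.1)
  # monotonicity of the bias in P_j
  pj <- seq(0.01, 0.9, length.out = 20)
  expect_true(all(diff(compute_bias(pj, 40)) > 0))
  expect_error(compute_weight(bcpnn_traces(bcpnn_params(), P_i = 0)),
               "trace-floor")
})

test_that("kappa = 0 freezes probability traces bit-exactly", {
  p <- bcpnn_params()
  tr <- bcpnn_traces(p, P_i = 0.123456789, P_j = 0.04, P_ij = 0.0062)
  tr[["Z_i"]] <- 0.8; tr[["E_ij"]] <- 0.3
  out <- bcpnn_propagate(tr, dt = 12345.6, p, kappa = 0)
  expect_identical(out[["P_i"]], tr[["P_i"]])
  expect_identical(out[["P_j"]], tr[["P_j"]])
  expect_identical(out[["P_ij"]], tr[["P_ij"]])
  # Z and E still evolve
  expect_lt(out[["Z_i"]], tr[["Z_i"]])
  # dense path freezes identically
  d <- update_traces(tr, 1, 0, kappa = 0, dt = 0.1, p)
  expect_identical(d[["P_ij"]], tr[["P_ij"]])
})

test_that("uncorrelated silence drives traces to the epsilon floor and weight to zero", {
  p <- bcpnn_params(tau_P = 2000)  # reduced tau_P for speed
  tr <- bcpnn_traces(p, P_i = 0.2, P_j = 0.2, P_ij = 0.04)
  out <- bcpnn_run_events(numeric(0), numeric(0), 60 * p$tau_P, p, kappa = 1)
  expect_equal(out[["Z_i"]], p$eps, tolerance = 1e-9)
  expect_equal(out[["P_i"]], p$eps, tolerance = 1e-6)
  expect_equal(out[["P_ij"]], p$eps^2, tolerance = 1e-6)
  expect_equal(compute_weight(out, 0.33), 0, tolerance = 1e-3)
})

test_that("exact event-driven propagation matches naive dense integration", {
  p <- bcpnn_params(t_spike = 0.01)
  set.seed(21)
  pre <- sort(runif(40, 0, 3000)); post <- sort(runif(35, 0, 3000))
  for (comp in c("ampa", "nmda")) {
    ev <- bcpnn_run_events(pre, post, 3000, p, kappa = 0.3,
                           component = comp)
    dn <- bcpnn_dense_oracle(pre, post, 3000, p, kappa = 0.3, dt = 0.01,
                             component = comp)
    rel <- abs(ev - dn) / pmax(abs(dn), 1e-8)
    expect_lt(max(rel), 0.02)
  }
})

test_that("independent Poisson trains drive the weight to zero within sampling error", {
  p <- bcpnn_params(tau_P = 2000)  # scaled-down probability trace
  set.seed(31)
  t_end <- 12 * p$tau_P
  f <- 10 / 1000  # 10 Hz in per-ms units
  ws <- vapply(1:8, function(r) {
    pre <- cumsum(rexp(ceiling(2 * f * t_end), f))
    post <- cumsum(rexp(ceiling(2 * f * t_end), f))
    out <- bcpnn_run_events(pre[pre < t_end], post[post < t_end], t_end,
                            p, kappa = 1)
    compute_weight(out, 1)
  }, numeric(1))
  expect_lt(abs(mean(ws)), 0.2)  # |log ratio| small on average
  # time-averaged Z approximately f / f_max + eps
  pre <- cumsum(rexp(ceiling(2 * f * t_end), f))
  out <- bcpnn_run_events(pre[pre < t_end], numeric(0), t_end, p,
                          kappa = 1, component = "nmda")
  expect_equal(out[["P_i"]], f / (p$f_max / 1000) + p$eps,
               tolerance = 0.15)
})

test_that("pre/post roles are exchangeable for identically distributed trains", {
  p <- bcpnn_params()
  set.seed(41)
  a <- sort(runif(30, 0, 2000)); b <- sort(runif(30, 0, 2000))
  fwd <- bcpnn_run_events(a, b, 2000, p, kappa = 0.5)
  rev <- bcpnn_run_events(b, a, 2000, p, kappa = 0.5)
  expect_equal(fwd[["P_ij"]], rev[["P_ij"]], tolerance = 1e-12)
  expect_equal(fwd[["P_i"]], rev[["P_j"]], tolerance = 1e-12)
})

test_that("probability traces stay bounded for saturating input", {
  p <- bcpnn_params(tau_P = 1000)
  # continuous 25 Hz (f_max) firing on both sides for a long time
  times <- seq(1, 20000, by = 40)
  out <- bcpnn_run_events(times, times, 20000, p, kappa = 1)
  expect_true(all(unclass(out) > 0))
  expect_lt(out[["P_i"]], 1.5)
  expect_lt(out[["P_j"]], 1.5)
})

test_that("eligibility traces carry pre-reward coactivity into a delayed reward window", {
  p <- bcpnn_params(tau_P = 10000)
  # synchronous co-firing burst, then silence, then a kappa boost that
  # starts 250 ms after the coactivation ended
  burst <- seq(1, 200, by = 10)
  gap <- 250
  run_with <- function(kappa_during_reward) {
    kap <- list(time = c(0, 200 + gap, 200 + gap + 250),
                value = c(p$kappa_normal, kappa_during_reward,
                          p$kappa_normal))
    bcpnn_run_events(burst, burst, 200 + gap + 500, p, kappa = kap)
  }
  rewarded <- run_with(p$kappa_reward)
  control <- run_with(p$kappa_normal)
  dP_r <- rewarded[["P_ij"]] - p$eps^2
  dP_c <- control[["P_ij"]] - p$eps^2
  expect_gt(dP_r / dP_c, 1.5)  # boosted learning credits the earlier burst
  # the co-eligibility at reward onset retains ~exp(-250/500) of its peak
  at_end <- bcpnn_run_events(burst, burst, 200, p, kappa = 0.3)
  at_reward <- bcpnn_propagate(at_end, gap, p, kappa = 0.3)
  ratio <- (at_reward[["E_ij"]] - p$eps^2) / (at_end[["E_ij"]] - p$eps^2)
  expect_equal(ratio, exp(-gap / p$tau_E), tolerance = 0.1)
})
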