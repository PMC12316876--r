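# Independent reference implementations used as oracles.  These are kept
# deliberately naive (dense fixed-step ODE integration, direct event
# iteration) and independent of the package's exact-propagation code paths.

# Dense fixed-step integration of the Tsodyks-Markram state over a spike
# train: du/dt = (U - u)/tau_A, dx/dt = (1 - x)/tau_D, with the jump
# u += U(1-u) before release and x -= u*x at each spike.
stp_dense_oracle <- function(spike_times, params, t_end = max(spike_times),
                             dt = 0.01) {
  u <- params$U; x <- 1
  out <- data.frame(t = spike_times, u = NA_real_, x = NA_real_,
                    release_gain = NA_real_)
  k <- 1L
  nstep <- ceiling(t_end / dt)
  da <- exp(-dt / params$tau_A); dd <- exp(-dt / params$tau_D)
  for (s in seq_len(nstep)) {
    t <- s * dt
    u <- params$U + (u - params$U) * da
    x <- 1 + (x - 1) * dd
    while (k <= length(spike_times) && spike_times[k] <= t) {
      u <- u + params$U * (1 - u)
      g <- u * x
      x <- x - g
      out$u[k] <- u; out$x[k] <- x; out$release_gain[k] <- g
      k <- k + 1L
    }
  }
  out
}

# Event-by-event exact iteration of the TM map (independent of the
# package's stp_on_spike, which it mirrors analytically).
stp_event_oracle <- function(spike_times, params) {
  u <- params$U; x <- 1; tl <- 0
  g <- numeric(length(spike_times))
  for (k in seq_along(spike_times)) {
    d <- spike_times[k] - tl
    u <- params$U + (u - params$U) * exp(-d / params$tau_A)
    x <- 1 + (x - 1) * exp(-d / params$tau_D)
    u <- u + params$U * (1 - u)
    g[k] <- u * x
    x <- x - g[k]
    tl <- spike_times[k]
  }
  g
}

# Naive dense integration of the full BCPNN trace cascade (explicit Euler
# at a fine step), spikes as one-step pulses of duration dt.
bcpnn_dense_oracle <- function(pre, post, t_end, params, kappa, dt = 0.01,
                               component = "ampa") {
  tau_z <- if (component == "ampa") params$tau_Z_ampa else params$tau_Z_nmda
  fm <- params$f_max / 1000
  amp <- 1 / (fm * dt)
  n <- ceiling(t_end / dt)
  Si <- Sj <- numeric(n)
  Si[pmin(pmax(ceiling(pre / dt), 1), n)] <- 1
  Sj[pmin(pmax(ceiling(post / dt), 1), n)] <- 1
  Zi <- Zj <- Ei <- Ej <- params$eps
  Eij <- params$eps^2
  Pi <- Pj <- params$eps; Pij <- params$eps^2
  for (k in seq_len(n)) {
    dZi <- (Si[k] * amp - Zi + params$eps) / tau_z
    dZj <- (Sj[k] * amp - Zj + params$eps) / tau_z
    dEi <- (Zi - Ei) / params$tau_E
    dEj <- (Zj - Ej) / params$tau_E
    dEij <- (Zi * Zj - Eij) / params$tau_E
    dPi <- kappa * (Ei - Pi) / params$tau_P
    dPj <- kappa * (Ej - Pj) / params$tau_P
    dPij <- kappa * (Eij - Pij) / params$tau_P
    Zi <- Zi + dt * dZi; Zj <- Zj + dt * dZj
    Ei <- Ei + dt * dEi; Ej <- Ej + dt * dEj; Eij <- Eij + dt * dEij
    Pi <- Pi + dt * dPi; Pj <- Pj + dt * dPj; Pij <- Pij + dt * dPij
  }
  c(Z_i = Zi, Z_j = Zj, E_i = Ei, E_j = Ej, E_ij = Eij,
    P_i = Pi, P_j = Pj, P_ij = Pij)
}

# Two-sided Fisher exact p-value by exhaustive hypergeometric enumeration.
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, r2, c1)
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A tiny preloaded reduced network shared across engine tests (built once
# per test run; kept small for speed).
tiny_network <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      np <- network_params("reduced", n_hc = 2, grid = c(2, 1),
                           mc_per_hc = 8, pyr_per_mc = 6, bask_per_mc = 2,
                           n_items = 8, n_contexts = 2)
      net <- build_network(np, seed = 7)
      net <- preload_attractors(net, preload_params(n_cycles = 4),
                                bcpnn_params(), seed = 8)
      cache <<- net
    }
    cache
  }
})
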