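#' Create a neuron state
#'
#' @param params neuron parameters ([neuron_params()])
#' @param n number of neurons
#' @param V_m initial membrane potential (mV); defaults to the leak reversal
#' @return a list of class `neuron_state` with vector fields
#' @export
neuron_state <- function(params, n = 1L, V_m = params$E_L) {
  structure(list(V_m = rep_len(V_m, n),
                 I_w = numeric(n),
                 I_beta = numeric(n),
                 refractory_remaining = numeric(n),
                 spike_count = integer(n)),
            class = "neuron_state")
}

#' Advance the AdEx membrane equation by one step
#'
#' Exponential-Euler integration of the linear (leak) part and forward Euler
#' for the exponential upstroke term and the currents.  During the
#' refractory period the membrane is clamped at the reset potential and only
#' the adaptation current decays.  The argument of the exponential term is
#' clamped at +20 before exponentiation to avoid overflow in pathological
#' states.
#'
#' All fields are vectorized over neurons.
#'
#' @param state a `neuron_state`
#' @param params a `neuron_params`
#' @param syn list with conductances `g_ampa`, `g_nmda`, `g_gaba` (nS) and a
#'   `receptor_params` under `receptor`; may be `NULL` for no synaptic input
#' @param I_ext external current (pA)
#' @param dt time step (ms)
#' @return the advanced `neuron_state`
#' @export
step_membrane <- function(state, params, syn = NULL, I_ext = 0, dt = 0.1) {
  stopifnot(dt > 0)
  V <- state$V_m
  active <- state$refractory_remaining <= 0

  I_syn <- 0
  if (!is.null(syn)) {
    r <- syn$receptor
    I_syn <- -(syn$g_ampa * (V - r$E_ampa) +
               syn$g_nmda * (V - r$E_nmda) +
               syn$g_gaba * (V - r$E_gaba))
  }
  expo <- pmin((V - params$V_t) / params$Delta_T, 20)
  I_exp <- params$g_L * params$Delta_T * exp(expo)
  I_tot <- I_exp + state$I_beta + I_syn + I_ext - state$I_w

  # exponential Euler on dV/dt = -(V - E_L)/tau_m + I_tot/C_m
  tau_m <- params$C_m / params$g_L
  decay <- exp(-dt / tau_m)
  V_inf <- params$E_L + I_tot / params$g_L
  V_new <- V_inf + (V - V_inf) * decay

  state$V_m <- ifelse(active, V_new, params$V_r)
  state$I_w <- state$I_w * exp(-dt / params$tau_Iw)
  state$refractory_remaining <- pmax(state$refractory_remaining - dt, 0)
  if (any(!is.finite(state$V_m)))
    stop("non-finite membrane potential: numerical blow-up")
  state
}

#' Detect spikes and apply reset
#'
#' Called after [step_membrane()].  A spike is declared when the membrane
#' potential exceeds the numerical cutoff `V_t + 10 * Delta_T`; the exact
#' cutoff is immaterial given the steep upstroke.  On a spike the membrane
#' is reset, the refractory clock armed, and the adaptation current
#' incremented by `b`.
#'
#' @inheritParams step_membrane
#' @return list with the updated `state` and logical vector `spiked`
#' @export
fire_and_reset <- function(state, params) {
  cutoff <- params$V_t + 10 * params$Delta_T
  spiked <- state$V_m > cutoff & state$refractory_remaining <= 0
  if (any(spiked)) {
    state$V_m[spiked] <- params$V_r
    state$refractory_remaining[spiked] <- params$tau_ref
    state$I_w[spiked] <- state$I_w[spiked] + params$b
    state$spike_count[spiked] <- state$spike_count[spiked] + 1L
  }
  list(state = state, spiked = spiked)
}

#' Simulate postsynaptic potentials for a set of synaptic weights
#'
#' Integrates one AdEx neuron per weight pair, held at `V_hold` by a
#' constant holding current, delivers a single presynaptic spike at
#' `t_spike` through the given AMPA/NMDA/GABA conductance amplitudes, and
#' returns the peak deflection from the holding potential.  Negative
#' weights are routed to the GABA channel.  Used to measure single-
#' connection EPSP/IPSP amplitudes of learned weights.
#'
#' @param w_ampa,w_nmda signed conductance amplitudes (nS); a negative
#'   value contributes its magnitude to the GABA channel
#' @param release_gain multiplicative short-term plasticity factor applied
#'   to the conductance amplitudes (scalar or vector)
#' @param V_hold holding potential (mV)
#' @param params neuron parameters
#' @param receptor receptor parameters
#' @param dt integration step (ms)
#' @param t_max simulated time after the spike (ms)
#' @return numeric vector of peak deflections (mV, signed)
#' @export
simulate_psp <- function(w_ampa, w_nmda = 0, release_gain = 1,
                         V_hold = NULL, params = neuron_params(),
                         receptor = receptor_params(),
                         dt = 0.1, t_max = 150) {
  n <- max(length(w_ampa), length(w_nmda))
  w_ampa <- rep_len(w_ampa, n); w_nmda <- rep_len(w_nmda, n)
  release_gain <- rep_len(release_gain, n)
  if (is.null(V_hold)) V_hold <- params$E_L
  I_hold <- params$g_L * (V_hold - params$E_L) -
    params$g_L * params$Delta_T * exp((V_hold - params$V_t) / params$Delta_T)

  g_ampa <- pmax(w_ampa, 0) * release_gain
  g_nmda <- pmax(w_nmda, 0) * release_gain
  g_gaba <- (pmax(-w_ampa, 0) + pmax(-w_nmda, 0)) * release_gain

  st <- neuron_state(params, n, V_m = V_hold)
  dA <- exp(-dt / receptor$tau_ampa)
  dN <- exp(-dt / receptor$tau_nmda)
  dG <- exp(-dt / receptor$tau_gaba)
  syn <- list(g_ampa = g_ampa, g_nmda = g_nmda, g_gaba = g_gaba,
              receptor = receptor)
  peak <- numeric(n)
  for (step in seq_len(ceiling(t_max / dt))) {
    st <- step_membrane(st, params, syn, I_ext = I_hold, dt = dt)
    syn$g_ampa <- syn$g_ampa * dA
    syn$g_nmda <- syn$g_nmda * dN
    syn$g_gaba <- syn$g_gaba * dG
    dev <- st$V_m - V_hold
    peak <- ifelse(abs(dev) > abs(peak), dev, peak)
  }
  peak
}
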