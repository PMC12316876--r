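#' Resting short-term plasticity state
#'
#' @param params an `stp_params`
#' @return list with utilization `u`, resources `x` and `t_last` (ms)
#' @export
stp_state <- function(params) {
  list(u = params$U, x = 1, t_last = 0)
}

#' Event-driven Tsodyks-Markram update at a spike arrival
#'
#' Relaxes the utilization `u` toward its baseline `U` (time constant
#' `tau_A`, augmentation) and the resources `x` toward 1 (time constant
#' `tau_D`, depression recovery) over the interval since the last update,
#' exactly, then applies the spike: the facilitation increment
#' `u <- u + U * (1 - u)` precedes release, the release gain is the
#' post-increment `u * x`, and the resources are depleted by that fraction.
#'
#' @param state list with `u`, `x`, `t_last` (see [stp_state()])
#' @param params an `stp_params`
#' @param t_spike spike arrival time (ms, not before `t_last`)
#' @return list with updated `state` and the `release_gain`
#' @export
stp_on_spike <- function(state, params, t_spike) {
  dt <- t_spike - state$t_last
  stopifnot(dt >= 0)
  u <- params$U + (state$u - params$U) * exp(-dt / params$tau_A)
  x <- 1 + (state$x - 1) * exp(-dt / params$tau_D)
  u <- u + params$U * (1 - u)
  gain <- u * x
  x <- x - gain
  list(state = list(u = u, x = x, t_last = t_spike), release_gain = gain)
}

#' Run the event-driven STP update over a spike train
#'
#' @param spike_times increasing spike arrival times (ms)
#' @param params an `stp_params`
#' @param state optional initial state (defaults to rest)
#' @return data frame with one row per spike: `t`, `u`, `x` (post-spike)
#'   and `release_gain`
#' @export
stp_train <- function(spike_times, params, state = stp_state(params)) {
  n <- length(spike_times)
  u <- x <- g <- numeric(n)
  for (k in seq_len(n)) {
    res <- stp_on_spike(state, params, spike_times[k])
    state <- res$state
    u[k] <- state$u; x[k] <- state$x; g[k] <- res$release_gain
  }
  data.frame(t = spike_times, u = u, x = x, release_gain = g)
}

#' Conductance increment for a delivered spike
#'
#' Routes a signed effective weight to the receptor channels: positive
#' weights increment the glutamatergic channel they belong to, negative
#' weights contribute their magnitude as positive conductance on the GABA
#' channel (disynaptic inhibition at the GABA reversal potential).
#'
#' @param g named numeric vector or list with `ampa`, `nmda`, `gaba`
#'   conductances (nS)
#' @param w_eff signed effective weight (nS)
#' @param release_gain short-term plasticity release gain
#' @param component `"ampa"` or `"nmda"` for positive weights
#' @return the updated conductance vector
#' @export
conductance_on_spike <- function(g, w_eff, release_gain = 1,
                                 component = c("ampa", "nmda")) {
  component <- match.arg(component)
  inc <- release_gain * abs(w_eff)
  if (w_eff >= 0) g[[component]] <- g[[component]] + inc
  else g[["gaba"]] <- g[["gaba"]] + inc
  g
}

#' Closed-form peak of a double-exponential postsynaptic potential
#'
#' Linearized passive-membrane oracle for single-synapse PSP amplitudes: a
#' conductance transient `g0 * exp(-t/tau_syn)` with constant driving force
#' `E_syn - V_hold` produces a membrane deflection whose peak is
#' `(g0 (E_syn - V_hold) tau_s tau_m / (C_m (tau_m - tau_s)))
#'  (exp(-t*/tau_m) - exp(-t*/tau_s))` at
#' `t* = tau_m tau_s log(tau_m/tau_s) / (tau_m - tau_s)`.
#' The degenerate case `tau_m = tau_s` is handled by the alpha-function
#' limit, which peaks at `t* = tau_m` with value
#' `g0 (E_syn - V_hold) tau_m exp(-1) / C_m`.
#'
#' @param g0 peak conductance (nS)
#' @param E_syn synaptic reversal potential (mV)
#' @param V_hold holding potential (mV)
#' @param tau_syn synaptic decay constant (ms)
#' @param C_m membrane capacitance (pF)
#' @param g_L leak conductance (nS)
#' @return peak deflection (mV, signed)
#' @export
psp_peak_closed_form <- function(g0, E_syn, V_hold, tau_syn,
                                 C_m = 280, g_L = 14) {
  tau_m <- C_m / g_L
  if (isTRUE(all.equal(tau_m, tau_syn))) {
    # limit tau_s -> tau_m of the double exponential: alpha function
    return(g0 * (E_syn - V_hold) * tau_m * exp(-1) / C_m)
  }
  tstar <- tau_m * tau_syn * log(tau_m / tau_syn) / (tau_m - tau_syn)
  g0 * (E_syn - V_hold) * tau_syn * tau_m / (C_m * (tau_m - tau_syn)) *
    (exp(-tstar / tau_m) - exp(-tstar / tau_syn))
}
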