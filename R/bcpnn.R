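#' Initial BCPNN trace set
#'
#' One full set of synaptic memory traces for a single connection and
#' component: fast pre/post activity traces `Z_i`, `Z_j`, eligibility
#' traces `E_i`, `E_j`, `E_ij` and probability traces `P_i`, `P_j`,
#' `P_ij`.  Two components (fast/AMPA and slow/NMDA) are normally kept per
#' connection, differing only in `tau_Z`.
#'
#' @param params a [bcpnn_params()]
#' @param P_i,P_j,P_ij initial probability traces (default: the epsilon
#'   floor and its independent product)
#' @return named numeric vector of class `bcpnn_traces`
#' @export
bcpnn_traces <- function(params, P_i = params$eps, P_j = params$eps,
                         P_ij = P_i * P_j) {
  structure(c(Z_i = params$eps, Z_j = params$eps,
              E_i = params$eps, E_j = params$eps, E_ij = params$eps^2,
              P_i = P_i, P_j = P_j, P_ij = P_ij),
            class = "bcpnn_traces")
}

#' Advance BCPNN traces over a spike-free interval
#'
#' Exact (closed-form) propagation of the linear trace cascade over `dt`
#' ms with a constant learning-rate factor `kappa`.  With `kappa = 0` the
#' probability traces are left bit-identical (weights and biases frozen).
#'
#' @param traces a [bcpnn_traces()] vector
#' @param dt interval length (ms)
#' @param params a [bcpnn_params()]
#' @param kappa learning-rate factor
#' @param component `"ampa"` or `"nmda"` (selects `tau_Z`)
#' @return the propagated trace vector
#' @export
bcpnn_propagate <- function(traces, dt, params, kappa = params$kappa_normal,
                            component = c("ampa", "nmda")) {
  component <- match.arg(component)
  tau_z <- if (component == "ampa") params$tau_Z_ampa else params$tau_Z_nmda
  out <- .cpp_prop_set(as.numeric(traces), dt, tau_z, params$tau_E,
                       params$tau_P, kappa, params$eps)
  names(out) <- names(traces)
  class(out) <- "bcpnn_traces"
  out
}

#' Apply a spike impulse to a Z trace
#'
#' The spike is a rectangular pulse of duration `t_spike` and height
#' `1 / (f_max t_spike)`; it is lumped into an instantaneous increment of
#' the pulse's terminal response, `(1/(f_max t_spike)) (1 - exp(-t_spike /
#' tau_Z))`, applied at the spike time.
#'
#' @inheritParams bcpnn_propagate
#' @param side `"pre"` (increments `Z_i`) or `"post"` (`Z_j`)
#' @return the updated trace vector
#' @export
bcpnn_spike <- function(traces, params, side = c("pre", "post"),
                        component = c("ampa", "nmda")) {
  side <- match.arg(side)
  component <- match.arg(component)
  tau_z <- if (component == "ampa") params$tau_Z_ampa else params$tau_Z_nmda
  f_max_ms <- params$f_max / 1000
  dZ <- (1 / (f_max_ms * params$t_spike)) *
    (1 - exp(-params$t_spike / tau_z))
  traces[[if (side == "pre") "Z_i" else "Z_j"]] <-
    traces[[if (side == "pre") "Z_i" else "Z_j"]] + dZ
  traces
}

#' Event-driven trace integration over explicit spike trains
#'
#' Integrates one component's trace set over pre- and postsynaptic spike
#' trains with a piecewise-constant kappa schedule, using exact
#' propagation between events.
#'
#' @inheritParams bcpnn_propagate
#' @param pre,post sorted spike times (ms)
#' @param t_end end of the integration interval (ms)
#' @param kappa either a single value or a list with `time` (segment start
#'   times, first `<= 0`) and `value`
#' @param init optional initial trace vector
#' @return the trace vector at `t_end`
#' @export
bcpnn_run_events <- function(pre, post, t_end, params,
                             kappa = params$kappa_normal,
                             component = c("ampa", "nmda"), init = NULL) {
  component <- match.arg(component)
  tau_z <- if (component == "ampa") params$tau_Z_ampa else params$tau_Z_nmda
  if (is.numeric(kappa) && length(kappa) == 1)
    kappa <- list(time = 0, value = kappa)
  out <- .cpp_run_traces(as.numeric(pre), as.numeric(post), t_end, tau_z,
                         params$tau_E, params$tau_P, params$eps,
                         params$f_max / 1000, params$t_spike,
                         as.numeric(kappa$time), as.numeric(kappa$value),
                         if (is.null(init)) numeric(0) else as.numeric(init))
  names(out) <- c("Z_i", "Z_j", "E_i", "E_j", "E_ij", "P_i", "P_j", "P_ij")
  class(out) <- "bcpnn_traces"
  out
}

#' One dense integration step of the trace cascade
#'
#' Reference per-step update (exponential integration of each stage with
#' its input held over the step): Z traces are driven by the spike pulse
#' indicator `S / (f_max t_spike) + eps`, E traces low-pass the Z traces
#' (`Z_i Z_j` for the co trace), and P traces low-pass the E traces at a
#' rate scaled by `kappa` (with `kappa = 0` they are left untouched).
#' `S_i`, `S_j` are pulse indicators: 1 while a spike pulse of duration
#' `t_spike` is active.  This dense path is the slow reference; the engine
#' uses the exact event-driven propagation, which is cross-checked against
#' it in the test suite.
#'
#' @inheritParams bcpnn_propagate
#' @param S_i,S_j pulse indicators (0 or 1) for this step
#' @return the updated trace vector
#' @export
update_traces <- function(traces, S_i, S_j, kappa, dt, params,
                          component = c("ampa", "nmda")) {
  component <- match.arg(component)
  tau_z <- if (component == "ampa") params$tau_Z_ampa else params$tau_Z_nmda
  f_max_ms <- params$f_max / 1000
  drive_i <- S_i / (f_max_ms * params$t_spike) + params$eps
  drive_j <- S_j / (f_max_ms * params$t_spike) + params$eps
  az <- exp(-dt / tau_z); ae <- exp(-dt / params$tau_E)
  ap <- exp(-kappa * dt / params$tau_P)
  t <- traces
  Zi0 <- t[["Z_i"]]; Zj0 <- t[["Z_j"]]
  t[["Z_i"]] <- drive_i + (Zi0 - drive_i) * az
  t[["Z_j"]] <- drive_j + (Zj0 - drive_j) * az
  t[["E_i"]] <- Zi0 + (t[["E_i"]] - Zi0) * ae
  t[["E_j"]] <- Zj0 + (t[["E_j"]] - Zj0) * ae
  t[["E_ij"]] <- Zi0 * Zj0 + (t[["E_ij"]] - Zi0 * Zj0) * ae
  if (kappa > 0) {
    t[["P_i"]] <- t[["E_i"]] + (t[["P_i"]] - t[["E_i"]]) * ap
    t[["P_j"]] <- t[["E_j"]] + (t[["P_j"]] - t[["E_j"]]) * ap
    t[["P_ij"]] <- t[["E_ij"]] + (t[["P_ij"]] - t[["E_ij"]]) * ap
  }
  t
}

#' BCPNN weight from probability traces
#'
#' `w = w_gain log(P_ij / (P_i P_j))`.  Zero when pre and post activity are
#' independent, positive for coactivation, negative for anti-correlated
#' activity (delivered as disynaptic inhibition at the GABA reversal).
#'
#' @param traces a [bcpnn_traces()] vector (or any object with `P_i`,
#'   `P_j`, `P_ij` entries)
#' @param w_gain weight gain (nS)
#' @return signed weight (nS)
#' @export
compute_weight <- function(traces, w_gain) {
  P_i <- traces[["P_i"]]; P_j <- traces[["P_j"]]; P_ij <- traces[["P_ij"]]
  if (any(c(P_i, P_j, P_ij) <= 0))
    stop("non-positive probability trace (trace-floor violation)")
  w_gain * log(P_ij / (P_i * P_j))
}

#' BCPNN intrinsic-excitability bias current
#'
#' `I_beta = beta_gain log(P_j)`: units with a high activation history are
#' intrinsically more excitable.
#'
#' @param P_j postsynaptic probability trace
#' @param beta_gain bias gain (pA)
#' @return bias current (pA)
#' @export
compute_bias <- function(P_j, beta_gain) {
  if (any(P_j <= 0))
    stop("non-positive probability trace (trace-floor violation)")
  beta_gain * log(P_j)
}
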