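#' Neuron model parameters
#'
#' Parameters of the adaptive exponential integrate-and-fire (AdEx) point
#' neuron used for both pyramidal and basket cells.  Subthreshold adaptation
#' is not modelled; spike-triggered adaptation enters through the increment
#' `b` of the adaptation current, which decays with time constant `tau_Iw`.
#' An intrinsic-excitability current `I_beta` (set by the plasticity rule,
#' see [compute_bias()]) is added to the membrane equation.
#'
#' @param C_m membrane capacitance (pF)
#' @param g_L leak conductance (nS)
#' @param E_L leak reversal potential (mV)
#' @param Delta_T spike upstroke slope factor (mV)
#' @param V_t spike threshold (mV)
#' @param V_r post-spike reset potential (mV)
#' @param tau_ref absolute refractory period (ms)
#' @param b spike-triggered adaptation current increment (pA)
#' @param tau_Iw adaptation current decay time constant (ms)
#' @return a list of class `neuron_params`
#' @export
neuron_params <- function(C_m = 280, g_L = 14, E_L = -70.6, Delta_T = 3,
                          V_t = -55, V_r = -60, tau_ref = 5,
                          b = 86, tau_Iw = 280) {
  stopifnot(C_m > 0, g_L > 0, tau_Iw > 0, tau_ref >= 0, V_r <= V_t)
  structure(list(C_m = C_m, g_L = g_L, E_L = E_L, Delta_T = Delta_T,
                 V_t = V_t, V_r = V_r, tau_ref = tau_ref,
                 b = b, tau_Iw = tau_Iw),
            class = "neuron_params")
}

#' Receptor (postsynaptic conductance) parameters
#'
#' Exponential-decay conductance transients per receptor type.  Negative
#' plastic weights are delivered as positive conductance on the GABA channel
#' (disynaptic inhibition through non-simulated double-bouquet cells).
#'
#' @param tau_ampa,tau_nmda,tau_gaba conductance decay constants (ms)
#' @param E_ampa,E_nmda,E_gaba reversal potentials (mV)
#' @return a list of class `receptor_params`
#' @export
receptor_params <- function(tau_ampa = 5, tau_nmda = 100, tau_gaba = 5,
                            E_ampa = 0, E_nmda = 0, E_gaba = -75) {
  stopifnot(tau_ampa > 0, tau_nmda > 0, tau_gaba > 0)
  structure(list(tau_ampa = tau_ampa, tau_nmda = tau_nmda, tau_gaba = tau_gaba,
                 E_ampa = E_ampa, E_nmda = E_nmda, E_gaba = E_gaba),
            class = "receptor_params")
}

#' Short-term plasticity (Tsodyks-Markram) parameters
#'
#' Presynaptic augmentation (utilization `u`, decaying to `U` with `tau_A`)
#' and depression (resources `x`, recovering to 1 with `tau_D`) applied to
#' glutamatergic synapses.  The release gain of a spike is `u * x` with the
#' facilitation increment applied before release.
#'
#' @param U baseline utilization increment (dimensionless, in (0, 1])
#' @param tau_A augmentation/facilitation decay time constant (ms)
#' @param tau_D depression recovery time constant (ms)
#' @return a list of class `stp_params`
#' @export
stp_params <- function(U = 0.2, tau_A = 5000, tau_D = 280) {
  stopifnot(U > 0, U <= 1, tau_A > 0, tau_D > 0)
  structure(list(U = U, tau_A = tau_A, tau_D = tau_D), class = "stp_params")
}

#' BCPNN learning-rule parameters
#'
#' Spike-based Bayesian-Hebbian plasticity.  Spiking activity is filtered
#' through a cascade of exponential traces Z (fast), E (eligibility) and P
#' (probability); weights are `w_gain * log(P_ij / (P_i P_j))` and the
#' intrinsic-excitability bias is `beta_gain * log(P_j)`.  Two trace
#' components are maintained per connection: a fast one (`tau_Z` equal to the
#' AMPA decay) and a slow one (NMDA decay).  The learning-rate factor kappa
#' scales the P-stage update only; `kappa = 0` freezes weights and biases.
#'
#' @param tau_Z_ampa,tau_Z_nmda Z-trace time constants (ms)
#' @param tau_E eligibility-trace time constant (ms)
#' @param tau_P probability-trace time constant (ms)
#' @param f_max maximal (normalizing) firing rate (Hz)
#' @param f_min lowest firing-rate estimate (Hz); retained for completeness,
#'   it enters no update equation
#' @param eps lowest attainable probability estimate (the additive floor of
#'   the Z traces)
#' @param t_spike spike-pulse duration used to normalize the spike impulse
#'   (ms)
#' @param w_gain_ampa,w_gain_nmda weight gains (nS)
#' @param beta_gain bias-current gain (pA)
#' @param kappa_normal baseline learning-rate factor
#' @param kappa_reward reward-modulated learning-rate factor
#' @param bias_component which trace component drives the bias
#'   (`"nmda"` (slower, rate-like; default) or `"ampa"`)
#' @return a list of class `bcpnn_params`
#' @export
bcpnn_params <- function(tau_Z_ampa = 5, tau_Z_nmda = 100,
                         tau_E = 500, tau_P = 30000,
                         f_max = 25, f_min = 0.2, eps = 0.0026,
                         t_spike = 1,
                         w_gain_ampa = 0.33, w_gain_nmda = 0.03,
                         beta_gain = 40,
                         kappa_normal = 0.3, kappa_reward = 1,
                         bias_component = c("nmda", "ampa")) {
  stopifnot(tau_Z_ampa > 0, tau_Z_nmda > 0, tau_E > 0, tau_P > 0,
            f_max > 0, eps > 0, eps < 1, t_spike > 0,
            kappa_normal >= 0, kappa_reward >= 0)
  structure(list(tau_Z_ampa = tau_Z_ampa, tau_Z_nmda = tau_Z_nmda,
                 tau_E = tau_E, tau_P = tau_P,
                 f_max = f_max, f_min = f_min, eps = eps, t_spike = t_spike,
                 w_gain_ampa = w_gain_ampa, w_gain_nmda = w_gain_nmda,
                 beta_gain = beta_gain,
                 kappa_normal = kappa_normal, kappa_reward = kappa_reward,
                 bias_component = match.arg(bias_component)),
            class = "bcpnn_params")
}

#' Stimulation-protocol parameters
#'
#' Background noise is delivered to every pyramidal cell as two independent
#' Poisson trains with opposing driving potentials (one exciting at the
#' glutamatergic reversal, one inhibiting at the GABA reversal), giving a
#' zero-mean conductance bombardment.  Cued patterns additionally receive a
#' specific excitatory Poisson drive.  Basket cells receive no background.
#'
#' @param r_bg background Poisson rate onto pyramidal cells (Hz, per
#'   generator)
#' @param g_bg background conductance transient amplitude (nS; applied as
#'   +g_bg excitatory and g_bg inhibitory)
#' @param r_stim stimulation Poisson rate (Hz)
#' @param g_stim stimulation conductance amplitude (nS, excitatory)
#' @param t_stim item stimulation duration (ms)
#' @param t_cue pre-reward re-stimulation duration (ms)
#' @param T_isi inter-stimulus interval within a trial (ms)
#' @param t_reward_delay delay from the end of the pre-reward cue to reward
#'   delivery (ms)
#' @param t_reward reward (elevated kappa) window duration (ms)
#' @param t_iti inter-trial interval (ms)
#' @param decision_threshold relative firing-rate margin for selecting the
#'   new item: new is selected iff `f_new < (1 - decision_threshold) * f_old`
#' @return a list of class `stim_params`
#' @export
stim_params <- function(r_bg = 470, g_bg = 1.5, r_stim = 340, g_stim = 1.5,
                        t_stim = 250, t_cue = 100, T_isi = 200,
                        t_reward_delay = 250, t_reward = 250, t_iti = 300,
                        decision_threshold = 0.15) {
  stopifnot(r_bg >= 0, r_stim >= 0, t_stim > 0, t_cue >= 0, T_isi >= 0,
            decision_threshold > 0, decision_threshold < 1)
  structure(list(r_bg = r_bg, g_bg = g_bg, r_stim = r_stim, g_stim = g_stim,
                 t_stim = t_stim, t_cue = t_cue, T_isi = T_isi,
                 t_reward_delay = t_reward_delay, t_reward = t_reward,
                 t_iti = t_iti, decision_threshold = decision_threshold),
            class = "stim_params")
}

#' Network layout and connectivity parameters
#'
#' Two reciprocally connected networks (Item and Context), each a square
#' grid of hypercolumns (HCs) of `mc_per_hc` minicolumns (MCs).  Memory
#' patterns claim one MC per HC.  Connection classes: recurrent
#' pyramidal-pyramidal within an MC (`cp_pp`), long-range pyramidal-
#' pyramidal across MCs of the same network (`cp_ppl`), associative
#' pyramidal-pyramidal between the networks (`cp_ppa`), and static
#' pyramidal/basket loops within an HC (`cp_pb`, `cp_bp`).
#'
#' The `"full"` profile reproduces the reference layout (9 HCs per network,
#' 16 MCs per HC, 30 pyramidal + 4 basket cells per MC: 8640 excitatory and
#' 1152 inhibitory cells in total).  The `"reduced"` profile is a
#' desk-scale configuration (4 HCs, 8 MCs per HC, 10 pyramidal + 2 basket
#' cells per MC) whose connection probabilities and static conductances are
#' recalibrated so that per-cell recurrent, associative and inhibitory input
#' remain in the operating regime of the full model despite the smaller
#' in-degrees (see the package vignette).
#'
#' @param scale `"full"` or `"reduced"`
#' @param n_items,n_contexts number of item/context memory patterns
#' @param ... named overrides of any field of the chosen profile
#' @return a list of class `network_params`
#' @export
network_params <- function(scale = c("full", "reduced"),
                           n_items = NULL, n_contexts = 2, ...) {
  scale <- match.arg(scale)
  p <- list(
    scale = scale,
    n_hc = 9, grid = c(3, 3), mc_per_hc = 16,
    pyr_per_mc = 30, bask_per_mc = 4,
    hc_diameter = 0.5,          # mm
    network_distance = 10,      # mm
    cp_pp = 0.2, cp_ppl = 0.2, cp_ppa = 0.04,
    cp_pb = 0.7, cp_bp = 0.7,
    g_pb = 3, g_bp = -7,        # nS, static pyramidal<->basket conductances
    v_axon = 0.2, v_myel = 2,   # m/s, conduction speeds
    t_min_syn = 1.5,            # ms, minimal synaptic delay
    # recalibration multipliers for scaled-down profiles (identity at
    # full scale): learned-weight and intrinsic-excitability gains and
    # background/stimulus drive
    gain_within = 1, gain_assoc = 1, gain_bias = 1,
    gain_bg = 1, gain_stim = 1
  )
  if (scale == "reduced") {
    p$n_hc <- 4; p$grid <- c(2, 2); p$mc_per_hc <- 8
    p$pyr_per_mc <- 10; p$bask_per_mc <- 2
    # recalibration: keep summed synaptic drive per cell comparable to the
    # full model (in-degree ratios; see vignette)
    p$cp_pp <- 0.5; p$cp_ppl <- 0.5; p$cp_ppa <- 0.2
    p$g_pb <- 6; p$g_bp <- -14
    p$gain_within <- 2.4; p$gain_assoc <- 16; p$gain_bias <- 3.0
    p$gain_bg <- 2.9; p$gain_stim <- 1.8
  }
  if (is.null(n_items)) n_items <- if (scale == "full") 16 else 8
  p$n_items <- n_items
  p$n_contexts <- n_contexts
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown network parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(p$n_items <= p$mc_per_hc, p$n_contexts <= p$mc_per_hc,
            p$cp_pp >= 0, p$cp_pp <= 1, p$cp_ppl >= 0, p$cp_ppl <= 1,
            p$cp_ppa >= 0, p$cp_ppa <= 1,
            p$cp_pb >= 0, p$cp_pb <= 1, p$cp_bp >= 0, p$cp_bp <= 1,
            prod(p$grid) == p$n_hc)
  class(p) <- "network_params"
  p
}

#' Attractor preloading (long-term training) parameters
#'
#' Protocol for embedding the item and context memory patterns as
#' within-network attractors by prior Bayesian-Hebbian learning.  Each
#' training cycle cues every pattern once, in shuffled order, for
#' `t_active` ms at rate `f_train`, separated by `t_gap` ms of silence; the
#' pattern duty cycle (`t_active` over the cycle period) sets the marginal
#' activation probability and thereby the attractor weight amplitude.  Cells
#' of a cued assembly fire in near-synchronous population bursts with
#' timing jitter `sigma_sync`, which differentiates fast-component
#' co-activation within an HC (short conduction delays) from across HCs.
#' Training uses a reduced learning-rate factor `kappa_train` so that the
#' effective averaging window `tau_P / kappa_train` spans several cycles.
#'
#' @param n_cycles number of shuffled training cycles
#' @param t_active per-pattern cue duration (ms)
#' @param t_gap silent gap between pattern cues (ms)
#' @param f_train population burst rate of cued assemblies during training
#'   (Hz, gamma-range: attractor activation proceeds in synchronized
#'   population cycles)
#' @param spikes_per_burst spikes emitted by each assembly cell around
#'   every population burst
#' @param sigma_sync within-assembly spike-time jitter around population
#'   burst times (ms)
#' @param kappa_train learning-rate factor during preloading
#' @return a list of class `preload_params`
#' @export
preload_params <- function(n_cycles = 12, t_active = 200, t_gap = 9000,
                           f_train = 40, spikes_per_burst = 4,
                           sigma_sync = 1.2, kappa_train = 0.05) {
  stopifnot(n_cycles >= 1, t_active > 0, t_gap >= 0, f_train > 0,
            spikes_per_burst >= 1, sigma_sync >= 0,
            kappa_train > 0, kappa_train <= 1)
  structure(list(n_cycles = n_cycles, t_active = t_active, t_gap = t_gap,
                 f_train = f_train, spikes_per_burst = spikes_per_burst,
                 sigma_sync = sigma_sync, kappa_train = kappa_train),
            class = "preload_params")
}

#' Full experiment configuration
#'
#' Bundles all parameter groups with their reference defaults, the task
#' variant, scale profile and seeds.  Any parameter group can be replaced by
#' a user-constructed one.
#'
#' @param variant task variant (see [generate_schedule()])
#' @param scale `"full"` or `"reduced"` network profile
#' @param seed master seed; all random substreams (connectivity, delays,
#'   preloading, schedule, noise) are derived from it
#' @param n_sessions number of simulated sessions (schedule/noise seeds are
#'   varied per session; the network is built and preloaded once)
#' @param dt integration step (ms)
#' @param neuron,receptor,stp,bcpnn,stim,network,preload parameter groups
#' @param record_spikes keep full spike rasters in the results
#' @return a list of class `experiment_config`
#' @export
experiment_config <- function(variant = "exp1_arr1",
                              scale = c("reduced", "full"),
                              seed = 1, n_sessions = 1, dt = 0.1,
                              neuron = neuron_params(),
                              receptor = receptor_params(),
                              stp = stp_params(),
                              bcpnn = bcpnn_params(),
                              stim = stim_params(),
                              network = NULL,
                              preload = preload_params(),
                              record_spikes = FALSE) {
  scale <- match.arg(scale)
  if (is.null(network)) network <- network_params(scale)
  if (scale == "reduced" && missing(bcpnn))
    # time compression of the intermediate-term plasticity constant to the
    # shortened session (see the vignette's scaled-down calibration notes)
    bcpnn <- bcpnn_params(tau_P = 5000)
  stopifnot(dt > 0, n_sessions >= 1)
  if (is.null(seed)) stop("a seed is required (reproducibility contract)")
  structure(list(variant = variant, scale = scale, seed = as.integer(seed),
                 n_sessions = n_sessions, dt = dt,
                 neuron = neuron, receptor = receptor, stp = stp,
                 bcpnn = bcpnn, stim = stim, network = network,
                 preload = preload, record_spikes = record_spikes),
            class = "experiment_config")
}

#' Derive named random substream seeds from a master seed
#'
#' Deterministic per-stream seeds (connectivity, delays, preloading,
#' schedules, noise, ...) so that every source of randomness in an
#' experiment traces back to one master seed.  Values stay below 2^31.
#'
#' @param seed master seed (integer)
#' @param n number of seeds to derive
#' @param stream stream name
#' @return integer vector of `n` seeds
#' @export
derive_seeds <- function(seed, n = 1L, stream = "") {
  h <- sum(utf8ToInt(paste0(stream, "#"))) * 7919L
  (as.integer(seed) * 48271L + h + 104729L * seq_len(n)) %% 2147483399L
}
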