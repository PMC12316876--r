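#' Create a simulation engine for a preloaded network
#'
#' Instantiates the clock-driven core: AdEx membranes, conductance
#' channels, the delayed spike ring buffer, Tsodyks-Markram state per
#' glutamatergic connection, frozen within-network weights (scaled by the
#' profile's recalibration gain) and full BCPNN trace sets on the
#' associative connections, initialized from the preloaded per-cell
#' traces so that associative weights start at zero.
#'
#' @param net a preloaded `bcpnn_network`
#' @param config an [experiment_config()]
#' @return an external pointer of class `bcpnn_engine`
#' @export
create_engine <- function(net, config) {
  stopifnot(isTRUE(net$preloaded))
  np <- net$params
  cfg <- config
  bias_comp <- if (cfg$bcpnn$bias_component == "ampa") 0L else 1L
  par <- list(
    dt = cfg$dt,
    C_m = cfg$neuron$C_m, g_L = cfg$neuron$g_L, E_L = cfg$neuron$E_L,
    Delta_T = cfg$neuron$Delta_T, V_t = cfg$neuron$V_t,
    V_r = cfg$neuron$V_r, tau_ref = cfg$neuron$tau_ref,
    b = cfg$neuron$b, tau_Iw = cfg$neuron$tau_Iw,
    tau_a = cfg$receptor$tau_ampa, tau_n = cfg$receptor$tau_nmda,
    tau_g = cfg$receptor$tau_gaba,
    E_a = cfg$receptor$E_ampa, E_n = cfg$receptor$E_nmda,
    E_g = cfg$receptor$E_gaba,
    U = cfg$stp$U, tau_A = cfg$stp$tau_A, tau_D = cfg$stp$tau_D,
    tau_z_a = cfg$bcpnn$tau_Z_ampa, tau_z_n = cfg$bcpnn$tau_Z_nmda,
    tau_e = cfg$bcpnn$tau_E, tau_p = cfg$bcpnn$tau_P,
    f_max_ms = cfg$bcpnn$f_max / 1000, eps = cfg$bcpnn$eps,
    t_spike = cfg$bcpnn$t_spike,
    w_gain_a = cfg$bcpnn$w_gain_ampa, w_gain_n = cfg$bcpnn$w_gain_nmda,
    beta_gain = cfg$bcpnn$beta_gain * np$gain_bias,
    kappa_normal = cfg$bcpnn$kappa_normal, bias_comp = bias_comp,
    r_bg_ms = cfg$stim$r_bg / 1000, g_bg = cfg$stim$g_bg * np$gain_bg,
    r_stim_ms = cfg$stim$r_stim / 1000,
    g_stim = cfg$stim$g_stim * np$gain_stim,
    gain_assoc = np$gain_assoc)
  co <- net$conns
  w_a <- co$w_ampa * ifelse(co$type == 0L, np$gain_within, 1)
  w_n <- co$w_nmda * ifelse(co$type == 0L, np$gain_within, 1)
  w_a[co$type == 2L] <- np$g_pb
  w_a[co$type == 3L] <- np$g_bp
  conns <- list(pre = as.integer(co$pre), post = as.integer(co$post),
                delay_steps = pmax(1L, as.integer(round(co$delay / cfg$dt))),
                type = as.integer(co$type), w_a = w_a, w_n = w_n)
  eng <- .cpp_engine_create(par, list(is_pyr = as.integer(net$cells$is_pyr)),
                            conns, list(cell_traces = net$cell_traces))
  attr(eng, "net") <- net
  attr(eng, "config") <- cfg
  class(eng) <- "bcpnn_engine"
  eng
}

#' Full tabular state snapshot
#'
#' Propagates every plastic trace to the current time and dumps the
#' associative connections (STP state, probability traces and weights per
#' component) together with the per-cell bias currents.
#'
#' @param engine a `bcpnn_engine`
#' @return list with `assoc` (data frame, one row per associative
#'   connection), `bias` (pA per cell) and `time_ms`
#' @export
snapshot_state <- function(engine) {
  list(assoc = .cpp_engine_snapshot_assoc(engine),
       bias = .cpp_engine_biases(engine),
       time_ms = .cpp_engine_time(engine))
}

#' Sever associative disynaptic inhibition
#'
#' Sets every between-network connection whose current weight (either
#' component) is negative to zero, silences it, and excludes it from
#' further learning.  Positive associative weights are untouched.
#'
#' @param engine a `bcpnn_engine`
#' @param what ablation target; only `"associative_disynaptic_inhibition"`
#'   is defined
#' @return the number of severed connections (invisibly)
#' @export
ablate <- function(engine, what = "associative_disynaptic_inhibition") {
  if (!identical(what, "associative_disynaptic_inhibition"))
    stop("unknown ablation key: ", what)
  invisible(.cpp_engine_ablate_neg_assoc(engine))
}

.assembly_cells <- function(net, pattern, network) {
  pattern_cells(net, pattern, network)
}

.window_rate <- function(engine, cells, window_ms) {
  cnt <- .cpp_engine_counts(engine)
  sum(cnt[cells + 1L]) / length(cells) / (window_ms / 1000)
}

#' Simulate one task session
#'
#' Runs a schedule through the engine trial by trial: the trial's context
#' assembly is cued throughout while the two items are stimulated
#' serially; trial-average rates of the two item assemblies over their own
#' stimulation windows feed the decision rule; on a rewarded choice the
#' chosen item is re-stimulated for the pre-reward cue and, after the
#' reward delay, the associative learning-rate factor is raised to
#' `kappa_reward` for the reward window (eligibility traces carry the
#' pre-reward co-activity into the boosted window).  A full snapshot of
#' the associative projection is taken at the start of the assessment
#' block.
#'
#' @param net a preloaded `bcpnn_network`
#' @param sched a `task_schedule`
#' @param config an [experiment_config()]
#' @param noise_seed seed for the session's Poisson noise streams
#' @param ablate_before_assessment sever associative disynaptic inhibition
#'   at the start of the assessment block
#' @param warmup_ms settling time before the first trial
#' @param engine optional pre-built engine (a fresh one is created
#'   otherwise; engines carry session state and must not be reused across
#'   sessions)
#' @return list of class `bcpnn_session` with `trials` (per-trial rates,
#'   choices and synaptic statistics), `results` (assessment trials only,
#'   the `TrialResult` table), `snapshot` (pre-assessment state),
#'   `within_weights_start`/`end` (frozen-weight invariance check),
#'   `spikes` (if recorded) and `schedule`
#' @export
run_session <- function(net, sched, config, noise_seed = config$seed,
                        ablate_before_assessment = FALSE,
                        warmup_ms = 500, engine = NULL) {
  cfg <- config
  if (is.null(engine)) engine <- create_engine(net, cfg)
  set.seed(noise_seed)
  if (cfg$record_spikes) .cpp_engine_record(engine, TRUE)
  stim <- cfg$stim
  thr <- stim$decision_threshold
  rule <- sched$reward_rule

  item_cells <- lapply(seq_len(cfg$network$n_items),
                       function(k) .assembly_cells(net, k, 1L))
  ctx_cells <- lapply(seq_len(max(sched$trials$context)),
                      function(k) .assembly_cells(net, k, 2L))

  w_start <- .cpp_engine_within_weights(engine)
  .cpp_engine_set_stim(engine, integer(0))
  .cpp_engine_advance(engine, warmup_ms)

  tr <- sched$trials
  out <- vector("list", nrow(tr))
  snapshot <- NULL
  in_assessment <- FALSE
  t0 <- .cpp_engine_time(engine)

  stim_window <- function(cells_on, measure_cells, dur) {
    .cpp_engine_set_stim(engine, cells_on)
    .cpp_engine_counts_reset(engine)
    .cpp_engine_advance(engine, .cpp_engine_time(engine) + dur)
    if (is.null(measure_cells)) NA_real_
    else .window_rate(engine, measure_cells, dur)
  }

  for (r in seq_len(nrow(tr))) {
    row <- tr[r, ]
    ctx <- ctx_cells[[row$context]]
    if (row$assess && !in_assessment) {
      in_assessment <- TRUE
      snapshot <- snapshot_state(engine)
      if (ablate_before_assessment) ablate(engine)
    }
    a_cells <- item_cells[[row$first]]
    b_cells <- item_cells[[row$second]]
    # per-item synaptic statistics before the trial's stimulation
    st_ab <- .cpp_engine_item_stats(engine, list(a_cells, b_cells))

    f_a <- stim_window(c(ctx, a_cells), a_cells, stim$t_stim)
    stim_window(ctx, NULL, stim$T_isi)
    f_b <- stim_window(c(ctx, b_cells), b_cells, stim$t_stim)
    stim_window(ctx, NULL, stim$T_isi)

    labeled <- !is.na(row$old_item) ||
      (row$first_status != row$second_status)
    if (labeled) {
      if (!is.na(row$old_item)) {
        old_is_first <- row$first == row$old_item
      } else {
        old_is_first <- row$first_status == "old"
      }
      f_old <- if (old_is_first) f_a else f_b
      f_new <- if (old_is_first) f_b else f_a
      dec <- decide_and_reward(f_old, f_new, thr, rule)
      choice_item <- if (dec$choice == "new") {
        if (old_is_first) row$second else row$first
      } else {
        if (old_is_first) row$first else row$second
      }
      rewarded <- !is.na(dec$reward_item)
    } else {
      # same-status pair (encoding): the lower-rate assembly is selected
      choice_item <- if (f_a <= f_b) row$first else row$second
      f_old <- f_new <- NA_real_
      dec <- list(choice = row$first_status, hit = NA)
      rewarded <- identical(row$first_status,
                            if (rule == "new") "new" else "old")
    }

    if (rewarded) {
      stim_window(c(ctx, item_cells[[choice_item]]), NULL, stim$t_cue)
      stim_window(ctx, NULL, stim$t_reward_delay)
      .cpp_engine_set_kappa(engine, cfg$bcpnn$kappa_reward)
      stim_window(ctx, NULL, stim$t_reward)
      .cpp_engine_set_kappa(engine, cfg$bcpnn$kappa_normal)
    } else {
      stim_window(ctx, NULL,
                  stim$t_cue + stim$t_reward_delay + stim$t_reward)
    }
    stim_window(ctx, NULL, stim$t_iti)

    out[[r]] <- data.frame(
      trial = row$trial, block = row$block, assess = row$assess,
      context = row$context,
      old_item = row$old_item, new_item = row$new_item,
      first = row$first, second = row$second,
      f_first = f_a, f_second = f_b,
      f_old = f_old, f_new = f_new,
      choice = dec$choice, hit = dec$hit, rewarded = rewarded,
      excluded = row$excluded,
      w_eff_first = st_ab[1, 1], bias_first = st_ab[1, 2],
      w_eff_second = st_ab[2, 1], bias_second = st_ab[2, 2])
  }
  .cpp_engine_set_stim(engine, integer(0))

  trials <- do.call(rbind, out)
  w_end <- .cpp_engine_within_weights(engine)
  res <- trials[trials$assess, ]
  structure(list(trials = trials, results = res, snapshot = snapshot,
                 within_weights_start = w_start, within_weights_end = w_end,
                 spikes = if (cfg$record_spikes)
                   .cpp_engine_spikes(engine, TRUE) else NULL,
                 schedule = sched, noise_seed = noise_seed,
                 t_start = t0, t_end = .cpp_engine_time(engine)),
            class = "bcpnn_session")
}
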