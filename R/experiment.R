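#' Run a full experiment
#'
#' Strings the pipeline together for one configuration: builds the
#' two-network model, preloads the long-term attractors, then simulates
#' `n_sessions` independent sessions of the chosen task variant (fresh
#' schedule and noise substreams per session, all derived from the master
#' seed) and aggregates the Memory Assessment trials into a performance
#' summary.
#'
#' @param config an [experiment_config()]
#' @param ablate_before_assessment sever the associative disynaptic
#'   inhibition at the start of every session's assessment block
#' @param net optional pre-built, preloaded network (built from the
#'   config's seed otherwise)
#' @param progress print per-session progress
#' @return list of class `bcpnn_experiment` with `performance`
#'   (a [performance_summary()] over pooled assessment pairs), `results`
#'   (pooled assessment trials), `trials` (all trials), `deltas`
#'   (pooled [pairwise_deltas()]), `sessions` (per-session summaries),
#'   `net`, `config`
#' @export
run_experiment <- function(config, ablate_before_assessment = FALSE,
                           net = NULL, progress = FALSE) {
  cfg <- config
  if (is.null(net)) {
    net <- build_network(network_params(cfg$scale),
                         seed = derive_seeds(cfg$seed, 1, "network"))
    net <- preload_attractors(net, cfg$preload, cfg$bcpnn,
                              seed = derive_seeds(cfg$seed, 1, "preload"))
  }
  sess <- vector("list", cfg$n_sessions)
  sched_seeds <- derive_seeds(cfg$seed, cfg$n_sessions, "schedule")
  noise_seeds <- derive_seeds(cfg$seed, cfg$n_sessions, "noise")
  for (s in seq_len(cfg$n_sessions)) {
    sched <- generate_schedule(cfg$variant, seed = sched_seeds[s],
                               n_items = cfg$network$n_items,
                               n_contexts = max(cfg$network$n_contexts,
                                 if (cfg$variant == "extra_context") 3L
                                 else 2L))
    sess[[s]] <- run_session(net, sched, cfg, noise_seed = noise_seeds[s],
                             ablate_before_assessment =
                               ablate_before_assessment)
    if (progress)
      message(sprintf("session %d/%d: %d/%d assessment hits", s,
                      cfg$n_sessions, sum(sess[[s]]$results$hit),
                      nrow(sess[[s]]$results)))
  }
  all_trials <- do.call(rbind, lapply(seq_along(sess), function(s) {
    cbind(session = s, sess[[s]]$trials)
  }))
  results <- do.call(rbind, lapply(seq_along(sess), function(s) {
    cbind(session = s, sess[[s]]$results)
  }))
  scored <- results[!results$excluded, ]
  deltas <- do.call(rbind, lapply(seq_along(sess), function(s) {
    cbind(session = s, pairwise_deltas(sess[[s]]))
  }))
  structure(list(performance = performance_summary(scored),
                 results = results, trials = all_trials, deltas = deltas,
                 sessions = lapply(sess, function(x)
                   list(schedule = x$schedule, noise_seed = x$noise_seed,
                        snapshot = x$snapshot)),
                 net = net, config = cfg),
            class = "bcpnn_experiment")
}

#' @export
print.bcpnn_experiment <- function(x, ...) {
  cat("Item-in-context experiment:", x$config$variant,
      sprintf("(%d session%s, scale %s)\n", x$config$n_sessions,
              if (x$config$n_sessions > 1) "s" else "", x$config$scale))
  print(x$performance)
  invisible(x)
}
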