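#' Sample axonal conduction delays
#'
#' Delay means are Euclidean distance over conduction speed plus the
#' minimal synaptic delay; samples are normal with a relative SD of 30% of
#' the mean (individual arborization differences), clamped below at the
#' minimal synaptic delay.
#'
#' @param dist Euclidean distances (mm)
#' @param speed conduction speed (m/s, i.e. mm/ms)
#' @param t_min_syn minimal synaptic delay (ms)
#' @return sampled delays (ms)
#' @export
sample_delay <- function(dist, speed, t_min_syn = 1.5) {
  stopifnot(all(is.finite(dist)), speed > 0)
  mu <- dist / speed + t_min_syn
  pmax(stats::rnorm(length(dist), mu, 0.3 * mu), t_min_syn)
}

# Sample directed connections from each pre cell to a candidate pool at
# probability cp, without materializing the full pair mask.
.draw_edges <- function(pre_ids, candidate_fn, cp) {
  if (cp <= 0) return(list(pre = integer(0), post = integer(0)))
  pre_out <- post_out <- vector("list", length(pre_ids))
  for (k in seq_along(pre_ids)) {
    cand <- candidate_fn(pre_ids[k])
    if (!length(cand)) next
    nk <- stats::rbinom(1, length(cand), cp)
    if (nk == 0) next
    tgt <- if (nk == length(cand)) cand else sample(cand, nk)
    pre_out[[k]] <- rep.int(pre_ids[k], nk)
    post_out[[k]] <- tgt
  }
  list(pre = unlist(pre_out, use.names = FALSE),
       post = unlist(post_out, use.names = FALSE))
}

#' Build the two-network model
#'
#' Instantiates the Item and Context networks on their hypercolumn grids,
#' scatters cells uniformly within each hypercolumn's disc, assigns every
#' minicolumn of each network to a memory pattern (one pattern-specific MC
#' per HC, non-overlapping), draws every connection class independently at
#' its probability, and samples conduction delays (myelinated, ten-fold
#' faster speed between the networks).
#'
#' Connection classes: recurrent pyramidal-pyramidal within an MC and
#' long-range pyramidal-pyramidal across MCs of the same network (plastic
#' during preloading, frozen during the task), associative
#' pyramidal-pyramidal between the networks (plastic throughout), and
#' static pyramidal/basket loops confined to the local HC.
#'
#' @param params a [network_params()]
#' @param seed integer seed (required; two builds with the same seed give
#'   identical edge lists)
#' @return a list of class `bcpnn_network` with elements `cells`
#'   (data frame: id, network, hc, mc, is_pyr, x, y, pattern),
#'   `conns` (data frame: pre, post, type, delay), `patterns`
#'   (per network, a list of data frames (hc, mc) per pattern), and
#'   `params`
#' @export
build_network <- function(params, seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required (reproducibility contract)")
  set.seed(seed)
  p <- params
  n_net <- 2L
  # hypercolumn centres on a grid with spacing = HC diameter
  gx <- rep(seq_len(p$grid[1]), p$grid[2]) - 1
  gy <- rep(seq_len(p$grid[2]), each = p$grid[1]) - 1
  hc_x <- gx * p$hc_diameter
  hc_y <- gy * p$hc_diameter

  per_mc <- p$pyr_per_mc + p$bask_per_mc
  per_hc <- p$mc_per_hc * per_mc
  per_net <- p$n_hc * per_hc
  n_cells <- n_net * per_net

  network <- rep(1:2, each = per_net)
  hc <- rep(rep(seq_len(p$n_hc), each = per_hc), n_net)
  mc <- rep(rep(rep(seq_len(p$mc_per_hc), each = per_mc), p$n_hc), n_net)
  is_pyr <- rep(rep(c(rep(TRUE, p$pyr_per_mc), rep(FALSE, p$bask_per_mc)),
                    p$mc_per_hc * p$n_hc), n_net)
  # uniform placement in the HC disc
  r <- (p$hc_diameter / 2) * sqrt(stats::runif(n_cells))
  th <- stats::runif(n_cells, 0, 2 * pi)
  x <- hc_x[hc] + r * cos(th) + (network - 1) * p$network_distance
  y <- hc_y[hc] + r * sin(th)

  # pattern assignment: a random permutation of MCs per HC per network;
  # pattern k claims one MC in every HC
  pattern_of_mc <- array(0L, dim = c(n_net, p$n_hc, p$mc_per_hc))
  patterns <- vector("list", n_net)
  for (g in 1:n_net) {
    patterns[[g]] <- vector("list", p$mc_per_hc)
    perm <- vapply(seq_len(p$n_hc), function(h) sample.int(p$mc_per_hc),
                   integer(p$mc_per_hc))
    for (k in seq_len(p$mc_per_hc)) {
      patterns[[g]][[k]] <- data.frame(hc = seq_len(p$n_hc),
                                       mc = perm[k, ])
      pattern_of_mc[cbind(g, seq_len(p$n_hc), perm[k, ])] <- k
    }
  }
  pattern <- pattern_of_mc[cbind(network, hc, mc)]
  pattern[!is_pyr] <- 0L

  cells <- data.frame(id = seq_len(n_cells) - 1L, network = network,
                      hc = hc, mc = mc, is_pyr = is_pyr,
                      x = x, y = y, pattern = pattern)

  pyr_ids <- cells$id[cells$is_pyr]
  bask_ids <- cells$id[!cells$is_pyr]
  key_mc <- (network - 1L) * (p$n_hc * p$mc_per_hc) +
    (hc - 1L) * p$mc_per_hc + (mc - 1L)
  key_hc <- (network - 1L) * p$n_hc + (hc - 1L)

  idx <- function(ids) ids + 1L
  edges <- list()
  # recurrent pyr-pyr within an MC
  e <- .draw_edges(pyr_ids, function(i) {
    s <- pyr_ids[key_mc[idx(pyr_ids)] == key_mc[i + 1L]]
    s[s != i]
  }, p$cp_pp)
  edges[[1]] <- data.frame(pre = e$pre, post = e$post, type = 0L)
  # long-range pyr-pyr within network, different MC
  e <- .draw_edges(pyr_ids, function(i) {
    s <- pyr_ids[network[idx(pyr_ids)] == network[i + 1L] &
                 key_mc[idx(pyr_ids)] != key_mc[i + 1L]]
    s
  }, p$cp_ppl)
  edges[[2]] <- data.frame(pre = e$pre, post = e$post, type = 0L)
  # associative pyr-pyr between networks (both directions)
  e <- .draw_edges(pyr_ids, function(i) {
    pyr_ids[network[idx(pyr_ids)] != network[i + 1L]]
  }, p$cp_ppa)
  edges[[3]] <- data.frame(pre = e$pre, post = e$post, type = 1L)
  # pyr -> basket within HC
  e <- .draw_edges(pyr_ids, function(i) {
    bask_ids[key_hc[idx(bask_ids)] == key_hc[i + 1L]]
  }, p$cp_pb)
  edges[[4]] <- data.frame(pre = e$pre, post = e$post, type = 2L)
  # basket -> pyr within HC
  e <- .draw_edges(bask_ids, function(i) {
    pyr_ids[key_hc[idx(pyr_ids)] == key_hc[i + 1L]]
  }, p$cp_bp)
  edges[[5]] <- data.frame(pre = e$pre, post = e$post, type = 3L)

  conns <- do.call(rbind, edges)
  dist <- sqrt((x[idx(conns$pre)] - x[idx(conns$post)])^2 +
               (y[idx(conns$pre)] - y[idx(conns$post)])^2)
  speed <- ifelse(conns$type == 1L, p$v_myel, p$v_axon)
  conns$delay <- sample_delay(dist, speed, p$t_min_syn)

  # locality validation: basket loops must stay within their HC
  pb <- conns$type %in% c(2L, 3L)
  if (any(key_hc[idx(conns$pre[pb])] != key_hc[idx(conns$post[pb])]))
    stop("construction validation failed: basket connectivity leaves its HC")

  structure(list(cells = cells, conns = conns, patterns = patterns,
                 params = p, seed = seed, preloaded = FALSE),
            class = "bcpnn_network")
}

#' @export
print.bcpnn_network <- function(x, ...) {
  cat("Two-network attractor model (", x$params$scale, " scale)\n", sep = "")
  cat("  cells: ", nrow(x$cells), " (", sum(x$cells$is_pyr), " pyramidal, ",
      sum(!x$cells$is_pyr), " basket)\n", sep = "")
  tab <- table(factor(x$conns$type, 0:3,
                      c("within", "associative", "pyr->basket",
                        "basket->pyr")))
  cat("  connections:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  cat("  preloaded:", x$preloaded, "\n")
  invisible(x)
}

#' Cells of a memory pattern's encoding assembly
#'
#' @param net a `bcpnn_network`
#' @param pattern pattern index
#' @param network 1 (Item) or 2 (Context)
#' @return integer cell ids (0-based engine ids)
#' @export
pattern_cells <- function(net, pattern, network = 1L) {
  cl <- net$cells
  cl$id[cl$is_pyr & cl$network == network & cl$pattern == pattern]
}

# Synthetic training spike trains: per cycle every pattern of a network is
# cued once (shuffled order) for t_active ms; cells of the cued assembly
# fire in near-synchronous population bursts at f_train with per-cell
# timing jitter sigma_sync.
.training_trains <- function(net, preload) {
  p <- net$params
  n_pat <- p$mc_per_hc
  slot <- preload$t_active + preload$t_gap
  cycle <- n_pat * slot
  t_end <- preload$n_cycles * cycle
  trains <- vector("list", nrow(net$cells))
  trains[] <- list(numeric(0))
  burst_offsets <- seq(0, preload$t_active - 1e-9, by = 1000 / preload$f_train)
  for (g in 1:2) {
    for (cyc in seq_len(preload$n_cycles)) {
      order_k <- sample.int(n_pat)
      for (s in seq_len(n_pat)) {
        k <- order_k[s]
        t0 <- (cyc - 1) * cycle + (s - 1) * slot
        cells <- pattern_cells(net, k, g)
        bursts <- rep(t0 + burst_offsets, each = preload$spikes_per_burst)
        for (cid in cells) {
          ts <- bursts + stats::rnorm(length(bursts), 0, preload$sigma_sync)
          ts <- sort(ts[ts > 0 & ts < t_end])
          trains[[cid + 1L]] <- c(trains[[cid + 1L]], ts)
        }
      }
    }
  }
  list(trains = lapply(trains, sort), t_end = t_end)
}

#' Preload long-term attractor memories
#'
#' Embeds the memory patterns as within-network attractors by offline
#' Bayesian-Hebbian training: every pattern of each network is cued in
#' shuffled order over several cycles (synthetic near-synchronous assembly
#' spike trains, see [preload_params()]), the trace cascade is integrated
#' exactly per connection (presynaptic spikes shifted by the conduction
#' delay), and the resulting weights are installed and frozen.  The
#' terminal per-cell traces initialize the intrinsic-excitability biases
#' and the associative trace marginals for the subsequent task.
#'
#' Because fast-component co-activation decays on the few-ms scale, the
#' short conduction delays within an HC yield stronger weights than the
#' longer delays across HCs, and patterns never cued together acquire
#' negative (disynaptic-inhibition) weights.
#'
#' @param net a `bcpnn_network`
#' @param preload a [preload_params()]
#' @param bcpnn a [bcpnn_params()]
#' @param seed integer seed for the training trains
#' @return the network with `conns$w_ampa`, `conns$w_nmda` filled for
#'   within-network connections, per-cell traces in `cell_traces`, and
#'   `preloaded = TRUE`
#' @export
preload_attractors <- function(net, preload = preload_params(),
                               bcpnn = bcpnn_params(), seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required (reproducibility contract)")
  for (g in 1:2) {
    pat <- net$patterns[[g]]
    claimed <- do.call(rbind, pat)
    if (anyDuplicated(claimed))
      stop("overlapping memory patterns are not supported")
  }
  set.seed(seed)
  tr <- .training_trains(net, preload)
  within <- net$conns$type == 0L
  w <- .cpp_preload_connections(
    tr$trains, net$conns$pre[within], net$conns$post[within],
    net$conns$delay[within], tr$t_end,
    bcpnn$tau_Z_ampa, bcpnn$tau_Z_nmda, bcpnn$tau_E, bcpnn$tau_P,
    bcpnn$eps, bcpnn$f_max / 1000, bcpnn$t_spike,
    preload$kappa_train, bcpnn$w_gain_ampa, bcpnn$w_gain_nmda)
  net$conns$w_ampa <- 0
  net$conns$w_nmda <- 0
  net$conns$w_ampa[within] <- w[, 4]
  net$conns$w_nmda[within] <- w[, 8]
  net$conns$frozen <- net$conns$type != 1L
  ct <- .cpp_cell_traces(tr$trains, tr$t_end,
                         bcpnn$tau_Z_ampa, bcpnn$tau_Z_nmda,
                         bcpnn$tau_E, bcpnn$tau_P, bcpnn$eps,
                         bcpnn$f_max / 1000, bcpnn$t_spike,
                         preload$kappa_train)
  colnames(ct) <- c("Z_ampa", "E_ampa", "P_ampa",
                    "Z_nmda", "E_nmda", "P_nmda")
  net$cell_traces <- ct
  net$preload <- preload
  net$preloaded <- TRUE
  net
}

#' Summarize preloaded within-network weights by connection class
#'
#' Mean total weight (AMPA + NMDA) of within-network pyramidal-pyramidal
#' connections split into same-pattern within-HC, same-pattern across-HC
#' and different-pattern classes.
#'
#' @param net a preloaded `bcpnn_network`
#' @return named numeric vector of class means (nS)
#' @export
weight_class_summary <- function(net) {
  stopifnot(isTRUE(net$preloaded))
  cl <- net$cells
  co <- net$conns[net$conns$type == 0L, ]
  pre1 <- co$pre + 1L; post1 <- co$post + 1L
  same_pat <- cl$pattern[pre1] == cl$pattern[post1]
  same_hc <- cl$hc[pre1] == cl$hc[post1]
  w <- co$w_ampa + co$w_nmda
  c(same_pattern_within_hc = mean(w[same_pat & same_hc]),
    same_pattern_across_hc = mean(w[same_pat & !same_hc]),
    different_pattern = mean(w[!same_pat]))
}

#' Measure single-connection PSPs of preloaded weights
#'
#' Delivers one presynaptic spike per sampled connection onto a cell
#' resting at the leak reversal (no bias current) and returns the peak
#' deflection, combining the AMPA and NMDA components with the first-spike
#' short-term plasticity release gain.
#'
#' @param net a preloaded `bcpnn_network`
#' @param class `"within_hc"` (same-pattern, same HC), `"across_hc"`,
#'   or `"different"` pattern
#' @param n_sample maximum number of sampled connections
#' @param neuron,receptor,stp parameter groups
#' @param V_hold holding potential (mV); default the leak reversal
#' @return numeric vector of peak PSPs (mV)
#' @export
measure_psp_sample <- function(net, class = c("within_hc", "across_hc",
                                              "different"),
                               n_sample = 200, neuron = neuron_params(),
                               receptor = receptor_params(),
                               stp = stp_params(), V_hold = NULL) {
  class <- match.arg(class)
  stopifnot(isTRUE(net$preloaded))
  cl <- net$cells
  co <- net$conns[net$conns$type == 0L, ]
  pre1 <- co$pre + 1L; post1 <- co$post + 1L
  same_pat <- cl$pattern[pre1] == cl$pattern[post1]
  same_hc <- cl$hc[pre1] == cl$hc[post1]
  sel <- switch(class,
                within_hc = same_pat & same_hc,
                across_hc = same_pat & !same_hc,
                different = !same_pat)
  co <- co[sel, ]
  if (nrow(co) > n_sample) co <- co[sample.int(nrow(co), n_sample), ]
  gain <- stp_on_spike(stp_state(stp), stp, 0)$release_gain
  simulate_psp(co$w_ampa, co$w_nmda, release_gain = gain,
               V_hold = V_hold, params = neuron, receptor = receptor)
}
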