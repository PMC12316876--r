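#' Trial-average firing rate of an assembly
#'
#' Spike count within the window over the assembly, divided by assembly
#' size and window length.
#'
#' @param spikes data frame with `time_ms` and `gid`
#' @param assembly integer cell ids
#' @param window numeric `c(t0, t1)` in ms
#' @return rate (Hz)
#' @export
trial_average_rate <- function(spikes, assembly, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  if (!length(assembly)) stop("empty assembly")
  n <- sum(spikes$gid %in% assembly &
           spikes$time_ms >= window[1] & spikes$time_ms < window[2])
  n / length(assembly) / ((window[2] - window[1]) / 1000)
}

#' Recall performance with Bernoulli SD
#'
#' Hit rate over trials, with the standard deviation derived from the
#' Bernoulli distribution of success probability scaled to percent:
#' `SD = 100 sqrt(p (1 - p) / n)`.
#'
#' @param trials data frame with a logical `hit` column (or a logical
#'   vector)
#' @return list of class `performance_summary`: `n`, `hits`, `mean` (%),
#'   `sd` (%)
#' @export
performance_summary <- function(trials) {
  hit <- if (is.data.frame(trials)) trials$hit else trials
  hit <- hit[!is.na(hit)]
  n <- length(hit)
  if (n < 1) stop("no trials")
  p <- mean(hit)
  structure(list(n = n, hits = sum(hit), mean = 100 * p,
                 sd = 100 * sqrt(p * (1 - p) / n)),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("hit rate: mean = %.2f%%, SD = %.2f%%, n = %d\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Pairwise old-minus-new differences per assessment trial
#'
#' For every (non-excluded) assessment pair: the difference in
#' trial-average firing rates; in mean effective within-network
#' connectivity of the two assemblies (static attractor weight times the
#' instantaneous short-term plasticity factor `u x`, AMPA and NMDA
#' components summed), taken just before the trial's stimulation; in mean
#' intrinsic-excitability bias; and in the trial index of the most recent
#' pre-assessment activation.
#'
#' @param session a `bcpnn_session` (or a row-bound `trials` table from
#'   several sessions with the same columns)
#' @param include_excluded keep pairs tagged excluded by the
#'   extra-context recency filter
#' @return data frame: trial, old_item, new_item, d_f, d_w, d_bias,
#'   d_trial
#' @export
pairwise_deltas <- function(session, include_excluded = FALSE) {
  tr <- if (inherits(session, "bcpnn_session")) session$trials else session
  res <- tr[tr$assess & !is.na(tr$old_item), ]
  if (!include_excluded) res <- res[!res$excluded, ]
  if (!nrow(res)) stop("no assessment trials")
  # most recent pre-assessment activation trial index per item
  d_trial <- vapply(seq_len(nrow(res)), function(k) {
    row <- res[k, ]
    pre <- tr[tr$trial < row$trial, ]
    t_old <- max(pre$trial[pre$first == row$old_item |
                           pre$second == row$old_item], -Inf)
    t_new <- max(pre$trial[pre$first == row$new_item |
                           pre$second == row$new_item], -Inf)
    t_old - t_new
  }, numeric(1))
  old_first <- res$first == res$old_item
  d_w <- ifelse(old_first, res$w_eff_first - res$w_eff_second,
                res$w_eff_second - res$w_eff_first)
  d_b <- ifelse(old_first, res$bias_first - res$bias_second,
                res$bias_second - res$bias_first)
  data.frame(trial = res$trial, old_item = res$old_item,
             new_item = res$new_item,
             d_f = res$f_old - res$f_new, d_w = d_w, d_bias = d_b,
             d_trial = d_trial)
}

#' Compare two conditions
#'
#' Two-sided hypothesis tests as used for the behavioral and synaptic
#' comparisons: Fisher's exact test on 2x2 hit/miss counts, the
#' Mann-Whitney U test (normal approximation with tie correction) and
#' Welch's two-sample t test.
#'
#' @param a,b for `"fisher"`: `performance_summary` objects (or logical
#'   hit vectors); for the sample tests: numeric vectors
#' @param test `"fisher"`, `"mannwhitney"` or `"ttest"`
#' @return list with `statistic`, `p_value` and the underlying `htest`
#' @export
compare_conditions <- function(a, b, test = c("fisher", "mannwhitney",
                                              "ttest")) {
  test <- match.arg(test)
  if (test == "fisher") {
    if (!inherits(a, "performance_summary")) a <- performance_summary(a)
    if (!inherits(b, "performance_summary")) b <- performance_summary(b)
    tab <- matrix(c(a$hits, a$n - a$hits, b$hits, b$n - b$hits), 2,
                  byrow = TRUE)
    if (any(tab < 0) || a$n == 0 || b$n == 0) stop("empty group")
    ht <- stats::fisher.test(tab, alternative = "two.sided")
    return(list(statistic = unname(ht$estimate), p_value = ht$p.value,
                htest = ht))
  }
  if (!length(a) || !length(b)) stop("empty group")
  ht <- switch(test,
    mannwhitney = stats::wilcox.test(a, b, exact = FALSE, correct = TRUE),
    ttest = stats::t.test(a, b, var.equal = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, htest = ht)
}
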