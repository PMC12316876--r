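#' Generate an item-in-context task schedule
#'
#' Builds the full trial sequence for one session of the chosen task
#' variant.  A trial is the serial stimulation of a pair of items while
#' the current context is continuously cued.  Items flip from new- to
#' old-in-context upon their first presentation in a context.
#'
#' Variants (`arr` = recency arrangement of the Memory Assessment pairs):
#' \describe{
#'   \item{`exp1_arr1`}{two context transitions (A, B, Assessment in A);
#'     every Assessment pair's new-in-A item was activated more recently
#'     than its old-in-A item (episodic memory in conflict with recency).}
#'   \item{`exp1_arr2`}{as `exp1_arr1`, but the old-in-A items are
#'     re-activated at the end of the context-B block, so recency favors
#'     them (synergy).}
#'   \item{`exp2_arr1`, `exp2_arr2`}{three context transitions
#'     (A, B, A, Assessment in B).}
#'   \item{`unbalanced`}{`exp1_arr1` with the future new-in-A items
#'     presented twice in context B.}
#'   \item{`extra_context`}{`exp1_arr1` with an extra context-C block
#'     (random half of the items) before Assessment; pairs whose old item
#'     ends up more recent are tagged `excluded` for Arrangement-1
#'     analysis.}
#'   \item{`reverse_reward`}{identical trial structure to `exp1_arr1`;
#'     reward attaches to old-in-context selections instead of
#'     new-in-context ones, repeatable per activation, so encoding-block
#'     trials (all new in their context) earn no reward.}
#' }
#'
#' Encoding pair composition (the reference description shows the pairing
#' structure but not a full enumeration): context-A presents its items
#' once each in same-status pairs; context-B presents the future old-in-A
#' items first, then the future new-in-A items, which realizes the
#' Arrangement-1 recency ordering for every admissible Assessment pairing
#' and keeps all pairs distinct throughout the task.
#'
#' @param variant one of `"exp1_arr1"`, `"exp1_arr2"`, `"exp2_arr1"`,
#'   `"exp2_arr2"`, `"unbalanced"`, `"extra_context"`, `"reverse_reward"`
#' @param seed integer seed (schedules are exactly reproducible from
#'   `(variant, seed)`)
#' @param n_items number of item patterns (even; half are withheld from
#'   the assessment context)
#' @param n_contexts number of context patterns available (3 required for
#'   `extra_context`)
#' @param max_retries bound on pairing resampling attempts
#' @return a list of class `task_schedule` with `trials` (data frame:
#'   trial, block, context, first, second, first_status, second_status,
#'   assess, old_item, new_item, excluded), `variant`, `reward_rule`,
#'   `arrangement`, `n_items`, `seed`
#' @export
generate_schedule <- function(variant = c("exp1_arr1", "exp1_arr2",
                                          "exp2_arr1", "exp2_arr2",
                                          "unbalanced", "extra_context",
                                          "reverse_reward"),
                              seed, n_items = 16, n_contexts = 2,
                              max_retries = 200) {
  variant <- match.arg(variant)
  if (missing(seed) || is.null(seed))
    stop("a seed is required (reproducibility contract)")
  stopifnot(n_items >= 4, n_items %% 4 == 0)
  if (variant == "extra_context" && n_contexts < 3)
    stop("extra_context requires three context patterns")
  set.seed(seed)

  items <- seq_len(n_items)
  half <- n_items / 2
  O <- sort(sample(items, half))   # encoded in the assessment context
  N <- setdiff(items, O)           # withheld (new at assessment)

  used_pairs <- character(0)
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  # presentation bookkeeping (the generator's own ledger)
  act_counter <- 0L
  last_act <- rep(NA_integer_, n_items)
  n_pres <- matrix(0L, n_items, max(n_contexts, 3))

  # column accumulators for the trial table
  col <- list(block = character(0), context = integer(0),
              first = integer(0), second = integer(0),
              first_status = character(0), second_status = character(0),
              assess = logical(0), old_item = integer(0),
              new_item = integer(0), excluded = logical(0))
  push_trial <- function(block, context, a, b, sa, sb, assess = FALSE,
                         old_item = NA_integer_, new_item = NA_integer_,
                         excluded = FALSE) {
    col$block[length(col$block) + 1L] <<- block
    col$context[length(col$context) + 1L] <<- context
    col$first[length(col$first) + 1L] <<- a
    col$second[length(col$second) + 1L] <<- b
    col$first_status[length(col$first_status) + 1L] <<- sa
    col$second_status[length(col$second_status) + 1L] <<- sb
    col$assess[length(col$assess) + 1L] <<- assess
    col$old_item[length(col$old_item) + 1L] <<- old_item
    col$new_item[length(col$new_item) + 1L] <<- new_item
    col$excluded[length(col$excluded) + 1L] <<- excluded
  }
  add_trials <- function(pairs, block, context) {
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      k <- pair_key(a, b)
      if (k %in% used_pairs) stop("internal: repeated pair")
      used_pairs <<- c(used_pairs, k)
      sa <- if (n_pres[a, context] > 0L) "old" else "new"
      sb <- if (n_pres[b, context] > 0L) "old" else "new"
      act_counter <<- act_counter + 1L; last_act[a] <<- act_counter
      n_pres[a, context] <<- n_pres[a, context] + 1L
      act_counter <<- act_counter + 1L; last_act[b] <<- act_counter
      n_pres[b, context] <<- n_pres[b, context] + 1L
      push_trial(block, context, a, b, sa, sb)
    }
  }
  shuffled_pairs <- function(set, forbid_repeats = TRUE) {
    for (try in seq_len(max_retries)) {
      s <- sample(set)
      p <- matrix(s, ncol = 2, byrow = TRUE)
      if (!forbid_repeats ||
          !any(pair_key(p[, 1], p[, 2]) %in% used_pairs))
        return(p)
    }
    stop("could not draw non-repeating pairs (max_retries exhausted)")
  }

  ctx_A <- 1L; ctx_B <- 2L; ctx_C <- 3L
  assess_ctx <- if (variant %in% c("exp2_arr1", "exp2_arr2")) ctx_B else ctx_A

  if (variant %in% c("exp2_arr1", "exp2_arr2")) {
    # three transitions: O in A, O in B, N in A, assessment in B
    add_trials(shuffled_pairs(O), "encoding_A", ctx_A)
    add_trials(shuffled_pairs(O), "encoding_B", ctx_B)
    add_trials(shuffled_pairs(N), "encoding_A2", ctx_A)
    if (variant == "exp2_arr2")
      add_trials(shuffled_pairs(O), "encoding_A2", ctx_A)
  } else {
    add_trials(shuffled_pairs(O), "encoding_A", ctx_A)
    add_trials(shuffled_pairs(O), "encoding_B", ctx_B)
    add_trials(shuffled_pairs(N), "encoding_B", ctx_B)
    if (variant == "exp1_arr2")
      add_trials(shuffled_pairs(O), "encoding_B", ctx_B)
    if (variant == "unbalanced")
      add_trials(shuffled_pairs(N), "encoding_B", ctx_B)
    if (variant == "extra_context")
      add_trials(shuffled_pairs(sample(items, half)), "encoding_C", ctx_C)
  }

  # --- Memory Assessment: match each withheld item with an encoded one ---
  arrangement <- if (variant %in% c("exp1_arr2", "exp2_arr2")) 2L else 1L
  news <- N   # withheld from the assessment context
  olds <- O
  pred_ok <- function(n_it, o_it) {
    if (arrangement == 1L) last_act[n_it] > last_act[o_it]
    else last_act[o_it] > last_act[n_it]
  }
  matching <- NULL
  for (try in seq_len(max_retries)) {
    perm <- sample(olds)
    ok <- mapply(pred_ok, news, perm)
    coll <- pair_key(news, perm) %in% used_pairs
    if (variant == "extra_context") {
      # predicate violations become excluded pairs rather than resamples
      if (!any(coll)) { matching <- perm; break }
    } else if (all(ok) && !any(coll)) { matching <- perm; break }
  }
  if (is.null(matching)) {
    # deterministic fallback: order both sides by recency
    matching <- olds[order(last_act[olds])]
    news <- news[order(last_act[news])]
    ok <- mapply(pred_ok, news, matching)
    if (variant != "extra_context" && !all(ok))
      stop("unsatisfiable arrangement constraint in assessment pairing")
  }
  ord <- sample(length(news))
  for (k in ord) {
    n_it <- news[k]; o_it <- matching[k]
    flip <- stats::runif(1) < 0.5
    a <- if (flip) n_it else o_it
    b <- if (flip) o_it else n_it
    excl <- variant == "extra_context" && !pred_ok(n_it, o_it)
    used_pairs <- c(used_pairs, pair_key(a, b))
    sa <- if (n_pres[a, assess_ctx] > 0L) "old" else "new"
    sb <- if (n_pres[b, assess_ctx] > 0L) "old" else "new"
    act_counter <- act_counter + 1L; last_act[a] <- act_counter
    n_pres[a, assess_ctx] <- n_pres[a, assess_ctx] + 1L
    act_counter <- act_counter + 1L; last_act[b] <- act_counter
    n_pres[b, assess_ctx] <- n_pres[b, assess_ctx] + 1L
    push_trial("assessment", assess_ctx, a, b, sa, sb, assess = TRUE,
               old_item = o_it, new_item = n_it, excluded = excl)
  }

  tr <- as.data.frame(col, stringsAsFactors = FALSE)
  tr$trial <- seq_len(nrow(tr))
  structure(list(trials = tr, variant = variant,
                 reward_rule = if (variant == "reverse_reward") "old"
                               else "new",
                 arrangement = arrangement, n_items = n_items,
                 n_contexts = n_contexts, seed = seed),
            class = "task_schedule")
}

#' @export
print.task_schedule <- function(x, ...) {
  cat("Task schedule:", x$variant, "(seed", x$seed, ")\n")
  print(table(x$trials$block))
  invisible(x)
}

#' Expand a schedule into a timed event table
#'
#' Flattens the trial sequence into ordered events (`context_on`,
#' `context_off`, `item_stim`, `assessment_marker`) with times from the
#' stimulation protocol: each item of a pair is cued for `t_stim` ms with
#' `T_isi` ms between stimuli; the post-decision window (pre-reward cue,
#' reward delay and reward window) is reserved after every trial.  Reward
#' events themselves depend on the simulated decisions and are appended to
#' the results at run time, not scheduled here.
#'
#' @param sched a `task_schedule`
#' @param stim a [stim_params()]
#' @return data frame: time_ms, kind, pattern, block, trial
#' @export
schedule_events <- function(sched, stim = stim_params()) {
  tm <- numeric(0); kd <- character(0); pt <- integer(0)
  bl <- character(0); tl <- integer(0)
  add <- function(time, kind, pattern, block, trial) {
    tm[length(tm) + 1L] <<- time; kd[length(kd) + 1L] <<- kind
    pt[length(pt) + 1L] <<- pattern; bl[length(bl) + 1L] <<- block
    tl[length(tl) + 1L] <<- trial
  }
  t <- 0
  cur_ctx <- NA_integer_
  trial_span <- 2 * stim$t_stim + 2 * stim$T_isi + stim$t_cue +
    stim$t_reward_delay + stim$t_reward + stim$t_iti
  tr <- sched$trials
  for (r in seq_len(nrow(tr))) {
    if (is.na(cur_ctx) || tr$context[r] != cur_ctx) {
      if (!is.na(cur_ctx))
        add(t, "context_off", cur_ctx, tr$block[r], tr$trial[r])
      add(t, "context_on", tr$context[r], tr$block[r], tr$trial[r])
      cur_ctx <- tr$context[r]
    }
    if (tr$assess[r])
      add(t, "assessment_marker", NA_integer_, tr$block[r], tr$trial[r])
    add(t, "item_stim", tr$first[r], tr$block[r], tr$trial[r])
    add(t + stim$t_stim + stim$T_isi, "item_stim", tr$second[r],
        tr$block[r], tr$trial[r])
    t <- t + trial_span
  }
  add(t, "context_off", cur_ctx, "end", NA_integer_)
  data.frame(time_ms = tm, kind = kd, pattern = pt, block = bl,
             trial = tl, stringsAsFactors = FALSE)
}

#' Independently validate a schedule
#'
#' Walks the expanded event list (not the generator's bookkeeping) and
#' re-derives item statuses and recency, then checks: a single active
#' context at every time; serial non-overlapping item stimulations; no
#' unordered pair repeated anywhere in the task; status transitions
#' monotone (new to old, never back); and the arrangement predicate of
#' every assessment pair (excluded pairs exempt for `extra_context`).
#'
#' @param sched a `task_schedule`
#' @param stim a [stim_params()]
#' @return `TRUE` (invisibly) or an error describing the violation
#' @export
validate_schedule <- function(sched, stim = stim_params()) {
  ev <- schedule_events(sched, stim)
  kind <- ev$kind; tms <- ev$time_ms; pat <- ev$pattern; trl <- ev$trial
  n_items <- sched$n_items
  seen <- matrix(FALSE, n_items, max(sched$n_contexts, 3))
  pair_seen <- character(0)
  ctx_open <- integer(0)
  cur_trial <- -1L
  trial_items <- integer(0)
  stim_end <- -Inf
  for (r in seq_along(kind)) {
    if (kind[r] == "context_on") {
      if (length(ctx_open)) stop("two contexts active simultaneously")
      ctx_open <- pat[r]
    } else if (kind[r] == "context_off") {
      if (!length(ctx_open) || ctx_open != pat[r])
        stop("context_off without matching context_on")
      ctx_open <- integer(0)
    } else if (kind[r] == "item_stim") {
      if (!length(ctx_open)) stop("item stimulation outside a context")
      if (tms[r] < stim_end) stop("overlapping item stimulations")
      stim_end <- tms[r] + stim$t_stim
      it <- pat[r]
      if (!identical(trl[r], cur_trial)) {
        cur_trial <- trl[r]; trial_items <- integer(0)
      }
      trial_items <- c(trial_items, it)
      if (length(trial_items) == 2L) {
        k <- paste(min(trial_items), max(trial_items))
        if (k %in% pair_seen) stop("pair repeated during the task")
        pair_seen <- c(pair_seen, k)
      }
      seen[it, ctx_open] <- TRUE
    }
  }
  # arrangement predicates, re-derived from event times
  is_stim <- kind == "item_stim"
  st_t <- tms[is_stim]; st_p <- pat[is_stim]; st_r <- trl[is_stim]
  tr <- sched$trials
  for (r in which(tr$assess)) {
    pre <- st_r < tr$trial[r]
    t_n <- max(st_t[pre & st_p == tr$new_item[r]])
    t_o <- max(st_t[pre & st_p == tr$old_item[r]])
    ok <- if (sched$arrangement == 1L) t_n > t_o else t_o > t_n
    if (!ok && !tr$excluded[r])
      stop("assessment pair violates its arrangement predicate")
    if (!seen[tr$old_item[r], tr$context[r]])
      stop("assessment old item never encoded in the assessment context")
  }
  invisible(TRUE)
}

#' Trial decision and reward rule
#'
#' New-in-context items are selected when their trial-average firing rate
#' is at least the decision margin below the pair-matched old-in-context
#' item's (the suppressed assembly disinhibits the downstream "new"
#' response channel).  Degenerate trials (both rates zero, or no margin
#' reached) count as errors.  Under the standard rule a hit rewards the
#' chosen new item; under the reverse rule (`rule = "old"`) the rewarded
#' category is the old item, identified through the same rate asymmetry,
#' and rewards repeat on every qualifying activation.
#'
#' @param f_old,f_new trial-average rates (Hz) of the old/new assemblies
#' @param threshold decision margin (default 0.15)
#' @param rule `"new"` (standard) or `"old"` (reverse rewarding)
#' @return list with `choice` (`"new"` or `"old"`), `hit` (logical) and
#'   `reward_item` (`"new"`, `"old"` or `NA` when no reward)
#' @export
decide_and_reward <- function(f_old, f_new, threshold = 0.15,
                              rule = c("new", "old")) {
  rule <- match.arg(rule)
  discriminated <- is.finite(f_old) && is.finite(f_new) &&
    (f_old > 0 || f_new > 0) && f_new < (1 - threshold) * f_old
  if (rule == "new") {
    choice <- if (discriminated) "new" else "old"
    hit <- discriminated
    reward_item <- if (hit) "new" else NA_character_
  } else {
    choice <- if (discriminated) "old" else "new"
    hit <- discriminated
    reward_item <- if (hit) "old" else NA_character_
  }
  list(choice = choice, hit = hit, reward_item = reward_item)
}
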