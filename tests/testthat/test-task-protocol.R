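variants <- c("exp1_arr1", "exp1_arr2", "exp2_arr1", "exp2_arr2",
              "unbalanced", "extra_context", "reverse_reward")

test_that("schedules are reproducible from (variant, seed) and validate", {
  for (v in variants) {
    a <- generate_schedule(v, seed = 101, n_contexts = 3)
    b <- generate_schedule(v, seed = 101, n_contexts = 3)
    expect_identical(a$trials, b$trials)
    expect_true(validate_schedule(a))
  }
  expect_error(generate_schedule("exp1_arr1"), "seed")
  expect_error(generate_schedule("extra_context", seed = 1,
                                 n_contexts = 2), "three context")
})

test_that("assessment pairs satisfy their arrangement predicate across many seeds", {
  for (v in c("exp1_arr1", "exp1_arr2", "unbalanced")) {
    for (s in 1:25) {
      sched <- generate_schedule(v, seed = s)
      expect_true(validate_schedule(sched))
    }
  }
})

test_that("assessment structure matches the task design", {
  sched <- generate_schedule("exp1_arr1", seed = 5, n_items = 16)
  tr <- sched$trials
  asmt <- tr[tr$assess, ]
  expect_equal(nrow(asmt), 8)
  enc_A <- unique(c(tr$first[tr$context == 1 & !tr$assess],
                    tr$second[tr$context == 1 & !tr$assess]))
  # every item withheld from context A assessed exactly once, each paired
  # with a distinct old-in-A item
  expect_equal(sort(asmt$new_item), sort(setdiff(1:16, enc_A)))
  expect_false(anyDuplicated(asmt$old_item) > 0)
  expect_true(all(asmt$old_item %in% enc_A))
})

test_that("item status flips to old after first presentation and never back", {
  for (v in variants) {
    sched <- generate_schedule(v, seed = 31, n_contexts = 3)
    tr <- sched$trials
    seen <- matrix(FALSE, sched$n_items, 3)
    for (r in seq_len(nrow(tr))) {
      for (side in c("first", "second")) {
        it <- tr[[side]][r]
        st <- tr[[paste0(side, "_status")]][r]
        expect_equal(st, if (seen[it, tr$context[r]]) "old" else "new")
        seen[it, tr$context[r]] <- TRUE
      }
    }
  }
})

test_that("no pair repeats between encoding and assessment", {
  for (s in 1:10) {
    sched <- generate_schedule("unbalanced", seed = 200 + s)
    tr <- sched$trials
    keys <- paste(pmin(tr$first, tr$second), pmax(tr$first, tr$second))
    expect_false(anyDuplicated(keys) > 0)
  }
})

test_that("unbalanced training doubles the withheld items' context-B exposure", {
  sched <- generate_schedule("unbalanced", seed = 77, n_items = 16)
  tr <- sched$trials
  news <- unique(tr$new_item[tr$assess])
  olds <- unique(tr$old_item[tr$assess])
  inB <- c(tr$first[tr$context == 2], tr$second[tr$context == 2])
  expect_true(all(table(inB[inB %in% news]) == 2))
  expect_true(all(table(inB[inB %in% olds]) == 1))
})

test_that("the decision rule selects new items on a 15% rate margin", {
  d <- decide_and_reward(20, 10)
  expect_equal(d$choice, "new"); expect_true(d$hit)
  expect_equal(d$reward_item, "new")
  d <- decide_and_reward(20, 19)
  expect_equal(d$choice, "old"); expect_false(d$hit)
  expect_true(is.na(d$reward_item))
  # degenerate trial: both rates zero scores as an error by convention
  d <- decide_and_reward(0, 0)
  expect_false(d$hit)
  # exact threshold is not a selection (strict inequality)
  d <- decide_and_reward(20, 17)
  expect_false(d$hit)
  # reverse rule: same discrimination, reward goes to the old item
  d <- decide_and_reward(20, 10, rule = "old")
  expect_equal(d$choice, "old"); expect_true(d$hit)
  expect_equal(d$reward_item, "old")
})

test_that("expanded event tables keep one context active and serial stimuli", {
  sched <- generate_schedule("exp2_arr2", seed = 9)
  ev <- schedule_events(sched)
  expect_true(all(diff(ev$time_ms) >= 0))
  n_on <- cumsum(ev$kind == "context_on") - cumsum(ev$kind == "context_off")
  expect_true(all(n_on %in% 0:1))
  stim <- ev[ev$kind == "item_stim", ]
  expect_true(all(diff(stim$time_ms) >= 200))  # inter-stimulus interval
})
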