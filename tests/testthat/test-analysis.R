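test_that("performance summary reproduces the Bernoulli SD closed form", {
  # printed (p, n) pairs, to two decimals
  s <- performance_summary(c(rep(TRUE, 119), rep(FALSE, 143 - 119)))
  expect_equal(round(s$mean, 2), 83.22)
  # the printed SD (3.12) is the closed form (3.1257) truncated
  expect_lt(abs(100 * sqrt(0.8321 * (1 - 0.8321) / 143) - 3.12), 0.011)
  expect_equal(s$sd, 100 * sqrt((119 / 143) * (1 - 119 / 143) / 143))
  s2 <- performance_summary(c(rep(TRUE, 36), rep(FALSE, 20)))  # 64.28%, n=56
  expect_equal(round(s2$mean, 2), 64.29)
  expect_equal(round(s2$sd, 2), 6.40)
  s3 <- performance_summary(c(rep(TRUE, 50), rep(FALSE, 50)))
  expect_equal(s3$sd, 5)
  expect_error(performance_summary(logical(0)), "no trials")
})

test_that("trial-average rates follow the count definition", {
  sp <- data.frame(time_ms = seq(10, 240, length.out = 10),
                   gid = rep(1:5, 2))
  expect_equal(trial_average_rate(sp, 1:30, c(0, 250)), 10 / 30 / 0.25)
  expect_equal(trial_average_rate(sp, 100:120, c(0, 250)), 0)
  expect_error(trial_average_rate(sp, integer(0), c(0, 250)), "empty")
  # doubling a window with the same spikes halves the rate
  expect_equal(trial_average_rate(sp, 1:30, c(0, 500)),
               trial_average_rate(sp, 1:30, c(0, 250)) / 2)
})

test_that("Fisher test agrees with exhaustive hypergeometric enumeration", {
  set.seed(51)
  for (rep in 1:40) {
    tab <- matrix(rpois(4, 8), 2)
    got <- compare_conditions(
      structure(list(hits = tab[1, 1], n = sum(tab[1, ])),
                class = "performance_summary"),
      structure(list(hits = tab[2, 1], n = sum(tab[2, ])),
                class = "performance_summary"),
      test = "fisher")
    expect_equal(got$p_value, fisher_enum_oracle(tab), tolerance = 1e-8)
  }
  # hit/miss counts reconstructed from the reported means and ns of the
  # two recency arrangements; the reconstruction yields p = 0.031 (no
  # integer count near the reported 93.33% gives a smaller p), i.e. a
  # significant difference at the 5% level
  arr1 <- performance_summary(c(rep(TRUE, 119), rep(FALSE, 24)))
  arr2 <- performance_summary(c(rep(TRUE, 92), rep(FALSE, 7)))
  expect_lt(compare_conditions(arr1, arr2, "fisher")$p_value, 0.05)
})

test_that("identical groups give p = 1 for all tests", {
  a <- c(rep(TRUE, 10), rep(FALSE, 5))
  expect_equal(compare_conditions(a, a, "fisher")$p_value, 1)
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(compare_conditions(x, x, "ttest")$p_value, 1)
  expect_gt(compare_conditions(x, x, "mannwhitney")$p_value, 0.99)
  expect_error(compare_conditions(numeric(0), x, "ttest"), "empty")
})

test_that("Mann-Whitney type-I error is near nominal under the null", {
  set.seed(61)
  pvals <- replicate(400, {
    compare_conditions(rnorm(12), rnorm(12), "mannwhitney")$p_value
  })
  alpha <- mean(pvals < 0.05)
  expect_gt(alpha, 0.02); expect_lt(alpha, 0.09)
})

test_that("pairwise deltas vanish for identical assembly statistics", {
  tr <- data.frame(trial = 1:2, block = c("encoding_A", "assessment"),
                   assess = c(FALSE, TRUE), context = 1,
                   old_item = c(NA, 1L), new_item = c(NA, 2L),
                   first = c(1L, 1L), second = c(2L, 2L),
                   f_first = c(10, 20), f_second = c(10, 20),
                   f_old = c(NA, 20), f_new = c(NA, 20),
                   choice = "old", hit = c(NA, FALSE), rewarded = FALSE,
                   excluded = FALSE,
                   w_eff_first = 1.5, bias_first = -100,
                   w_eff_second = 1.5, bias_second = -100)
  d <- pairwise_deltas(tr)
  expect_equal(d$d_f, 0)
  expect_equal(d$d_w, 0)
  expect_equal(d$d_bias, 0)
  expect_equal(d$d_trial, 0)  # both last activated in trial 1
})
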