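mk_trials <- function(rt, correct, subject = "s1", group = "g") {
  data.frame(subject = subject, group = group,
             trial_index = seq_along(rt), condition = "intact",
             response = ifelse(correct, "correct", "incorrect"),
             rt_ms = rt, stringsAsFactors = FALSE)
}

test_that("subject summaries use all trials for accuracy, correct trials for RT", {
  tr <- mk_trials(rep(1500, 204), c(rep(TRUE, 102), rep(FALSE, 102)))
  s <- summarize_subjects(tr)
  expect_equal(s$accuracy_pct, 50)
  tr2 <- mk_trials(c(1000, 2000, 9999), c(TRUE, TRUE, FALSE))
  expect_equal(summarize_subjects(tr2)$mean_correct_rt_ms, 1500)
  # non-responses count as incorrect
  tr3 <- tr2; tr3$response[3] <- "none"
  expect_equal(summarize_subjects(tr3)$accuracy_pct, 100 * 2 / 3)
  # no correct trials: RT undefined and flagged
  tr4 <- mk_trials(c(1000, 2000), c(FALSE, FALSE))
  s4 <- summarize_subjects(tr4)
  expect_true(is.na(s4$mean_correct_rt_ms))
  expect_true(s4$no_correct_trials)
  expect_error(summarize_subjects(tr4[0, ]), "at least one")
  dup <- rbind(tr2, tr2[1, ])
  expect_error(summarize_subjects(dup), "duplicate")
})

test_that("pooled t is correct, antisymmetric and unit invariant", {
  expect_equal(pooled_t(1, 1, 2, 0, 1, 2)$t, 1)
  expect_equal(pooled_t(5, 2, 9, 5, 3, 14)$t, 0)
  a <- pooled_t(10, 2, 8, 12, 3, 9)
  b <- pooled_t(12, 3, 9, 10, 2, 8)
  expect_equal(a$t, -b$t)
  expect_equal(a$df, 15)
  # common affine rescaling of both groups leaves t unchanged
  cc <- pooled_t(10 * 3 + 7, 2 * 3, 8, 12 * 3 + 7, 3 * 3, 9)
  expect_equal(cc$t, a$t)
  # degenerate SDs
  z <- pooled_t(1, 0, 4, 1, 0, 4)
  expect_equal(z$t, 0); expect_true(z$degenerate)
  inf <- pooled_t(2, 0, 4, 1, 0, 4)
  expect_true(is.infinite(inf$t) && inf$t > 0)
  # Welch variant reduces df under variance imbalance
  w <- pooled_t(10, 1, 10, 12, 5, 10, welch = TRUE)
  expect_lt(w$df, 18)
})

test_that("split-half RTs follow the trial index", {
  tr <- mk_trials(rep(1500, 204), rep(TRUE, 204))
  sh <- split_half_rt(tr)
  expect_equal(c(sh$rt_first_half, sh$rt_second_half), c(1500, 1500))
  tr2 <- mk_trials(seq(2000, 1000, length.out = 204), rep(TRUE, 204))
  sh2 <- split_half_rt(tr2)
  expect_gt(sh2$rt_first_half, sh2$rt_second_half)
  expect_warning(split_half_rt(mk_trials(rep(1500, 100), rep(TRUE, 100))),
                 "proportionally")
})

test_that("the generator's planted practice effect is recovered", {
  cfg <- sim_config(n_per_group = 150, n_channels = 2, n_trials = 204,
                    p_fast = 0, practice_ms = 134)
  tr <- simulate_trials(cfg, seed = 41)
  sh <- split_half_rt(tr)
  diff <- mean(sh$rt_first_half - sh$rt_second_half)
  expect_lt(abs(diff - 134), 20)
})

test_that("response-locked selection keeps correct trials slower than 1 s", {
  tr <- mk_trials(c(500, 1000, 1001, 2000), rep(TRUE, 4))
  sel <- select_response_locked(tr)
  expect_equal(sort(sel$trials$rt_ms), c(1001, 2000))
  expect_equal(sel$counts$n_retained, 2L)
  # boundary is strict and incorrect trials are dropped
  tr2 <- mk_trials(c(900, 1000), rep(TRUE, 2))
  expect_equal(select_response_locked(tr2)$counts$n_retained, 0L)
  tr3 <- mk_trials(c(1500, 1600), c(TRUE, FALSE))
  expect_equal(nrow(select_response_locked(tr3)$trials), 1L)
})

test_that("the retained fraction matches the generator's fast-guess model", {
  cfg <- sim_config(n_per_group = 50, n_channels = 2, n_trials = 204,
                    p_fast = 0.1, practice_ms = 0)
  ds <- simulate_power_dataset(cfg, seed = 42)
  sel <- select_response_locked(ds$trials)
  s <- summarize_subjects(ds$trials)
  observed <- sum(sel$counts$n_retained) / sum(s$n_correct)
  # expected: survive the fast-guess mixture and the log-normal tail
  loc <- ds$ground_truth$rt_location
  expected <- mean((1 - 0.1) * (1 - plnorm(1000, loc, cfg$sdlog_trial)))
  expect_lt(abs(observed - expected), 0.03)
  expect_gt(observed, 0.8)
})

test_that("the 2.5 SD outlier rule flags strictly and self-shields at tiny n", {
  v <- c(1, 1, 1, 100)
  expect_false(any(outlier_flag(v)))   # SD inflated by the candidate itself
  expect_equal(abs(100 - mean(v)) < 2.5 * sd(v), TRUE)
  expect_false(any(outlier_flag(rep(7, 5))))
  # a value exactly at k SD is not flagged (strict inequality)
  x <- c(rnorm(20), 9)
  k_edge <- max(abs(x - mean(x)) / sd(x))
  expect_false(any(outlier_flag(x, k = k_edge)))
  expect_true(any(outlier_flag(x, k = k_edge * 0.999)))
  expect_error(outlier_flag(c(1, 2)), "3")
})

test_that("group statistics assemble means, SDs and pooled t per measure", {
  cfg <- sim_config(n_per_group = 16, n_channels = 2, n_trials = 204)
  ds <- simulate_power_dataset(cfg, seed = 43)
  bt <- behaviour_table(ds$trials, ds$subjects)
  gs <- behaviour_group_stats(bt)
  expect_equal(gs$measure,
               c("hipp_volume_mm3", "accuracy_pct", "mean_rt_ms"))
  expect_equal(gs$df, rep(30, 3))
  expect_true(all(is.finite(gs$t)))
  # behaviour table round trip through delimited text
  f <- tempfile(fileext = ".tsv")
  write_behaviour_table(bt, f)
  bt2 <- read_behaviour_table(f)
  expect_equal(bt2$mean_rt_ms, bt$mean_rt_ms)
  expect_identical(bt2$subject, bt$subject)
})
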