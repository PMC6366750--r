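test_that("identical config and seed give bit-identical datasets", {
  cfg <- small_config(effects = list(effect_spec(1, "alpha", "delay", -1)))
  a <- simulate_power_dataset(cfg, seed = 5)
  b <- simulate_power_dataset(cfg, seed = 5)
  expect_identical(a$power$values, b$power$values)
  expect_identical(a$trials, b$trials)
  expect_identical(a$subjects, b$subjects)
  c <- simulate_power_dataset(cfg, seed = 6)
  expect_false(identical(a$power$values, c$power$values))
})

test_that("with zero planted effects the condition contrast is null", {
  cfg <- sim_config(n_per_group = 30, n_channels = 10, n_trials = 20,
                    conditions = c("pre_stimulus", "delay"))
  ds <- simulate_power_dataset(cfg, seed = 11, include_trials = FALSE)
  con <- condition_contrast(ds$power, "delay", "pre_stimulus")
  tvals <- apply(con, c(2, 3), function(v) {
    mean(v) / (sd(v) / sqrt(length(v)))
  })
  expect_lt(max(abs(tvals)), 4.5)
  expect_lt(mean(abs(tvals)), 1.5)
  expect_lt(mean(abs(tvals) > qt(0.975, 59)), 0.2)
})

test_that("planted effect sizes are recovered at large n", {
  # -1.5 SD test-phase decrease in 20 of 25 channels (alpha) for the older
  # group; per-channel between-group effect size in the test condition
  # should converge to the planted magnitude
  cfg <- sim_config(n_per_group = 200, n_channels = 25, n_trials = 20,
                    conditions = c("first_study", "test"),
                    effects = list(effect_spec(1:20, "alpha", "test", -1.5,
                                               group = "older")))
  ds <- simulate_power_dataset(cfg, seed = 21, include_trials = FALSE)
  vals <- ds$power$values[, "test", , "alpha"]
  old <- ds$power$group[rownames(vals)] == "older"
  d_hat <- vapply(seq_len(25), function(ch) {
    x <- vals[old, ch]; y <- vals[!old, ch]
    (mean(x) - mean(y)) / sqrt((var(x) + var(y)) / 2)
  }, 0)
  expect_true(all(abs(d_hat[1:20] - (-1.5)) < 0.3))
  expect_true(all(abs(d_hat[21:25]) < 0.3))
})

test_that("planted brain-behaviour coupling attains the configured r", {
  cfg <- sim_config(n_per_group = 200, n_channels = 20, n_trials = 60,
                    p_fast = 0, conditions = c("first_study", "test"),
                    coupling = coupling_spec("older", 1:15, "alpha", "test",
                                             "first_study", r = 0.6))
  ds <- simulate_power_dataset(cfg, seed = 7)
  con <- condition_contrast(ds$power, "test", "first_study")
  mc <- rowMeans(con[, 1:15, "alpha"])
  bt <- behaviour_table(ds$trials, ds$subjects)
  old <- bt$group == "older"
  expect_lt(abs(cor(mc[old], log(bt$mean_rt_ms[old])) - 0.6), 0.1)
  expect_lt(abs(cor(mc[!old], log(bt$mean_rt_ms[!old]))), 0.25)
})

test_that("simulated accuracies follow the configured group distribution", {
  cfg <- sim_config(n_per_group = 100, n_channels = 2, n_trials = 204,
                    conditions = c("pre_stimulus", "delay"))
  tr <- simulate_trials(cfg, seed = 3)
  s <- summarize_subjects(tr)
  young <- s$group == "younger"
  expect_lt(abs(mean(s$accuracy_pct[young]) - 82.5), 2.5)
  expect_gt(sd(s$accuracy_pct[young]), 7)
  expect_lt(sd(s$accuracy_pct[young]), 13)
  expect_true(all(s$accuracy_pct >= 0 & s$accuracy_pct <= 100))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_per_group = 1), "n_per_group")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(small_config(effects = list(
    effect_spec(99, "alpha", "delay", 1))), "channel")
  expect_error(small_config(effects = list(
    effect_spec(1, "gamma", "delay", 1))), "band")
  expect_error(small_config(effects = list(
    effect_spec(1, "alpha", "retrieval", 1))), "condition")
  expect_error(coupling_spec("older", 1, "alpha", "test", r = 1), "\\|r\\|")
  expect_error(sim_config(bands = list(band_definition("a", 2, 8),
                                       band_definition("b", 7, 12))),
               "overlap")
  # coupling too weak to reach the requested correlation
  expect_error(small_config(coupling = coupling_spec(
    "older", 1, "alpha", "delay", "pre_stimulus", r = 0.95,
    strength = 0.1)), "unattainable")
})

test_that("ground truth records the planted structure", {
  cfg <- small_config(effects = list(effect_spec(2, "beta", "delay", -2,
                                                 group = "older")),
                      coupling = coupling_spec("older", 1, "theta", "delay",
                                               "pre_stimulus", r = 0.4))
  ds <- simulate_power_dataset(cfg, seed = 9, include_trials = FALSE)
  gt <- ds$ground_truth
  s <- gt$cell_sd
  expect_equal(s, sqrt(cfg$noise_sd^2 + cfg$subject_sd^2))
  E <- gt$expected_cell_means
  expect_equal(E$older["delay", 2, "beta"] - E$older["pre_stimulus", 2, "beta"],
               -2 * s)
  expect_equal(E$younger["delay", 2, "beta"],
               E$younger["pre_stimulus", 2, "beta"])
  expect_equal(gt$coupling$r, 0.4)
  # ground truth serialises to JSON
  f <- tempfile(fileext = ".json")
  write_ground_truth(gt, f)
  expect_true(file.exists(f))
  expect_silent(jsonlite::read_json(f))
})

test_that("linear-power mode exponentiates the log-power draw", {
  cfg_log <- small_config()
  cfg_lin <- small_config(log_power = FALSE)
  a <- simulate_power_dataset(cfg_log, seed = 4, include_trials = FALSE)
  b <- simulate_power_dataset(cfg_lin, seed = 4, include_trials = FALSE)
  expect_equal(exp(a$power$values), b$power$values)
  expect_true(all(b$power$values > 0))
})
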