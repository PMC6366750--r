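test_that("a pure tone concentrates power at its frequency", {
  fs <- 64; n <- 512
  t <- (seq_len(n) - 1) / fs
  x <- matrix(sin(2 * pi * 10 * t), 1)
  tfr <- compute_tfr(x, fs, window_points = 64, n_windows = 30)
  spec <- apply(tfr$power[1, , , drop = FALSE], 2, mean)
  near <- abs(tfr$freq - 10) <= 2
  expect_gte(sum(spec[near]) / sum(spec), 0.90)
  expect_equal(tfr$freq[which.max(spec)], 10)
  # band power: theta nearly empty next to alpha
  th <- band_window_power(tfr, band_definition("theta", 2, 7),
                          range(tfr$time))
  al <- band_window_power(tfr, band_definition("alpha", 9, 14),
                          range(tfr$time))
  expect_lt(th / al, 0.01)
})

test_that("all-zero signals give an all-zero TFR", {
  tfr <- compute_tfr(matrix(0, 2, 300), fs = 50, window_points = 64,
                     n_windows = 5)
  expect_true(all(tfr$power == 0))
})

test_that("the short-time average matches an independent DFT periodogram", {
  set.seed(42)
  sig <- array(rnorm(3 * 2 * 512), c(3, 2, 512))
  tfr <- compute_tfr(sig, fs = 128, window_points = 64, n_windows = 15)
  ora <- oracle_tfr(sig, fs = 128, wp = 64, nw = 15)
  expect_lt(max(abs(tfr$power - ora)) / max(ora), 1e-6)
})

test_that("the mean white-noise spectrum is flat", {
  set.seed(1)
  sig <- array(rnorm(400 * 1 * 512), c(400, 1, 512))
  tfr <- compute_tfr(sig, fs = 128, window_points = 64, n_windows = 15)
  spec <- apply(tfr$power[1, , , drop = FALSE], 2, mean)
  inner <- spec[2:(length(spec) - 1)]  # DC/Nyquist bins are single-sided
  expect_lt(max(abs(inner - mean(inner))) / mean(inner), 0.10)
})

test_that("power scales as amplitude squared and averages linearly over trials", {
  set.seed(8)
  sig <- array(rnorm(4 * 1 * 300), c(4, 1, 300))
  tfr1 <- compute_tfr(sig, fs = 50, window_points = 64, n_windows = 8)
  tfr3 <- compute_tfr(3 * sig, fs = 50, window_points = 64, n_windows = 8)
  expect_equal(tfr3$power, 9 * tfr1$power, tolerance = 1e-12)
  ta <- compute_tfr(sig[1:3, , , drop = FALSE], fs = 50,
                    window_points = 64, n_windows = 8)
  tb <- compute_tfr(sig[4, , , drop = FALSE], fs = 50,
                    window_points = 64, n_windows = 8)
  expect_equal(tfr1$power, (3 * ta$power + tb$power) / 4, tolerance = 1e-12)
  expect_true(all(tfr1$power >= 0))
})

test_that("band/window averaging follows the closed interval bin-centre rule", {
  # synthetic TFR: 1 channel, freq 1..10 Hz, time 0.5..9.5 s, power = time
  freq <- 1:10
  time <- seq(0.5, 9.5, by = 1)
  pow <- array(rep(time, each = 10), c(1, 10, 10))
  tfr <- structure(list(power = pow, freq = freq, time = time, fs = 20,
                        window_points = 16, n_windows = 10, n_trials = 1),
                   class = "tfr")
  # band and window spanning everything = grand mean
  expect_equal(band_window_power(tfr, band_definition("all", 1, 10),
                                 c(0.5, 9.5)),
               mean(pow))
  # linear ramp in time: window mean equals the ramp at the centre of the
  # included bin centres (within half a bin of the window midpoint)
  got <- band_window_power(tfr, band_definition("all", 1, 10), c(2, 6.4))
  centres <- time[time >= 2 & time <= 6.4]
  expect_equal(unname(got), mean(centres))
  expect_lt(abs(got - mean(c(2, 6.4))), 0.5 + 1e-12)
  # empty selections error
  expect_error(band_window_power(tfr, band_definition("none", 10.2, 10.9),
                                 c(0.5, 9.5)), "frequency")
  expect_error(band_window_power(tfr, band_definition("all", 1, 10),
                                 c(9.6, 9.9)), "time")
})

test_that("window contrasts subtract elementwise with axis checking", {
  a <- array(rnorm(24), c(2, 3, 4),
             dimnames = list(s = c("s1", "s2"), c = c("c1", "c2", "c3"),
                             b = paste0("b", 1:4)))
  expect_true(all(window_contrast(a, a) == 0))
  expect_equal(window_contrast(a + 2, a), array(2, dim(a), dimnames(a)))
  bad <- a[, 1:2, ]
  expect_error(window_contrast(a, bad), "axis mismatch")
  bad2 <- a; dimnames(bad2)[[2]] <- c("x", "y", "z")
  expect_error(window_contrast(a, bad2), "axis mismatch")
})

test_that("simulated carriers put power in their own band", {
  cfg <- sim_config(n_per_group = 2, n_channels = 2, n_trials = 4,
                    timecourse = list(fs = 128, background_rms = 0,
                                      carriers = list(list(
                                        channels = 1, band = "alpha",
                                        base_amp = 1,
                                        gains = c(pre_stimulus = 1, study = 1,
                                                  delay = 1, test = 1)))))
  tc <- simulate_timecourses(cfg, seed = 2, n_trials = 4, n_channels = 2)
  tfr <- compute_tfr(tc$signals, tc$fs, window_points = 64, n_windows = 100,
                     t0 = tc$time[1])
  al <- band_window_power(tfr, band_definition("alpha", 9, 14), c(0.5, 8.5))
  th <- band_window_power(tfr, band_definition("theta", 2, 7), c(0.5, 8.5))
  expect_gt(al[1] / th[1], 10)
  expect_equal(unname(al[2]), 0)  # carrier only on channel 1, no background
})

test_that("zero carriers and zero background give zero signals", {
  cfg <- sim_config(n_per_group = 2, n_channels = 2, n_trials = 2,
                    timecourse = list(fs = 64, background_rms = 0,
                                      carriers = list()))
  tc <- simulate_timecourses(cfg, seed = 1, n_trials = 2, n_channels = 1)
  expect_true(all(tc$signals == 0))
  tfr <- compute_tfr(tc$signals, tc$fs, window_points = 64, n_windows = 10)
  expect_true(all(tfr$power == 0))
})

test_that("a planted delay-phase amplitude drop is recovered as log power ratio", {
  # alpha amplitude halves in the delay phase: power ratio 0.25.  Windows
  # are kept clear of phase boundaries by more than half a segment.
  cfg <- sim_config(n_per_group = 2, n_channels = 1, n_trials = 4,
                    timecourse = list(fs = 128, background_rms = 0.02,
                                      carriers = list(list(
                                        channels = 1, band = "alpha",
                                        base_amp = 1,
                                        gains = c(pre_stimulus = 1, study = 1,
                                                  delay = 0.5, test = 1)))))
  tc <- simulate_timecourses(cfg, seed = 3, n_trials = 100, n_channels = 1)
  tfr <- compute_tfr(tc$signals, tc$fs, window_points = 64, n_windows = 200,
                     t0 = tc$time[1])
  alpha <- band_definition("alpha", 9, 14)
  p_delay <- band_window_power(tfr, alpha, c(10.0, 10.25))
  p_pre <- band_window_power(tfr, alpha, c(-0.5, -0.25))
  expect_lt(abs(log(p_delay / p_pre) - log(0.25)), 0.1 * abs(log(0.25)))
})

test_that("an amplitude drop yields negative contrasts in nearly all trial sets", {
  cfg <- sim_config(n_per_group = 2, n_channels = 1, n_trials = 4,
                    timecourse = list(fs = 128, background_rms = 0.3,
                                      carriers = list(list(
                                        channels = 1, band = "alpha",
                                        base_amp = 1,
                                        gains = c(pre_stimulus = 1, study = 1,
                                                  delay = 0.5, test = 1)))))
  alpha <- band_definition("alpha", 9, 14)
  signs <- vapply(1:20, function(s) {
    tc <- simulate_timecourses(cfg, seed = 100 + s, n_trials = 6,
                               n_channels = 1)
    tfr <- compute_tfr(tc$signals, tc$fs, window_points = 64,
                       n_windows = 120, t0 = tc$time[1])
    sign(log(band_window_power(tfr, alpha, c(10.0, 10.25))) -
           log(band_window_power(tfr, alpha, c(-0.5, -0.25))))
  }, 0)
  expect_gte(mean(signs < 0), 0.95)
})

test_that("spectral input validation catches bad calls", {
  expect_error(compute_tfr(matrix(0, 1, 50), fs = 50, window_points = 64,
                           n_windows = 5), "shorter")
  expect_error(compute_tfr(matrix(0, 1, 300), fs = -1), "fs")
  expect_error(band_definition("x", 5, 3), "f_lo")
  expect_error(band_definition("x", 0, 3), "f_lo")
  cfg <- sim_config(n_per_group = 2, n_channels = 1, n_trials = 2,
                    timecourse = list(fs = 20, background_rms = 0,
                                      carriers = list(list(
                                        channels = 1, band = "beta",
                                        gains = c(pre_stimulus = 1, study = 1,
                                                  delay = 1, test = 1)))))
  expect_error(simulate_timecourses(cfg, seed = 1, n_channels = 1),
               "Nyquist")
})
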