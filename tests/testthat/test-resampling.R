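test_that("a maximal planted effect yields permutation p = 0", {
  # near-noiseless condition effect in 16 subjects: the chance that a
  # random within-subject reassignment reproduces the planted partition is
  # 2 / 2^16, so no sampled permutation reaches the observed sigma
  set.seed(1)
  n <- 16
  Xa <- matrix(rnorm(n * 4, sd = 1e-3), n)
  Xb <- matrix(rnorm(n * 4, sd = 1e-3), n) + 10
  tm <- make_tm_two_cond(Xa, Xb)
  perm <- pls_permutation(tm, n_perm = 500, seed = 2)
  expect_equal(perm$perm_p[1], 0)
})

test_that("Monte-Carlo permutation p matches exhaustive enumeration", {
  set.seed(3)
  n <- 3
  Xa <- matrix(rnorm(n * 3), n)
  Xb <- matrix(rnorm(n * 3), n) + 0.8
  tm <- make_tm_two_cond(Xa, Xb)
  n_perm <- 4000
  # subject-respecting scheme vs the 2^n within-subject swap enumeration
  exact <- oracle_exhaustive_perm_p(Xa, Xb)
  mc <- pls_permutation(tm, n_perm = n_perm, seed = 4)
  tol <- 4 * sqrt(exact[1] * (1 - exact[1]) / n_perm) + 2 / n_perm
  expect_lt(abs(mc$perm_p[1] - exact[1]), tol)
  # literal row-relabelling scheme vs the choose(2n, n) enumeration
  exact_r <- oracle_exhaustive_perm_p_rows(rbind(Xa, Xb), n)
  mc_r <- pls_permutation(tm, n_perm = n_perm, seed = 5, scheme = "rows")
  tol_r <- 4 * sqrt(exact_r[1] * (1 - exact_r[1]) / n_perm) + 2 / n_perm
  expect_lt(abs(mc_r$perm_p[1] - exact_r[1]), tol_r)
})

test_that("permutation options behave as documented", {
  tm <- rand_task_matrix(5)
  expect_error(pls_permutation(tm, n_perm = 0), "n_perm")
  p0 <- pls_permutation(tm, n_perm = 50, seed = 1)
  p1 <- pls_permutation(tm, n_perm = 50, seed = 1)
  expect_identical(p0$perm_p, p1$perm_p)
  ps <- pls_permutation(tm, n_perm = 50, seed = 1, add_one = TRUE)
  expect_true(all(ps$perm_p >= 1 / 51))
  for (sch in c("conditions_only", "rows")) {
    pw <- pls_permutation(tm, n_perm = 50, seed = 1, scheme = sch)
    expect_true(all(pw$perm_p >= 0 & pw$perm_p <= 1))
  }
})

test_that("identical subjects give zero bootstrap SEs, flagged", {
  row <- c(1, 2, 3)
  Xa <- rbind(row, row, row, row)
  Xb <- rbind(row + 1, row + 1, row + 1, row + 1)
  tm <- make_tm_two_cond(Xa, Xb)
  fit <- mean_centered_pls(tm)
  boot <- pls_bootstrap(tm, fit, n_boot = 20, seed = 1)
  expect_true(all(boot$boot_se == 0))
  expect_true(boot$degenerate_se)
  expect_true(all(is.na(boot$boot_ratio)))
  expect_false(any(is.na(boot$boot_ci_lo)))
})

test_that("with two draws the percentile CI is their min and max", {
  tm <- rand_task_matrix(7)
  fit <- mean_centered_pls(tm)
  boot <- pls_bootstrap(tm, fit, n_boot = 2, seed = 9, keep_draws = TRUE)
  lo <- pmin(boot$draws[, , 1], boot$draws[, , 2])
  hi <- pmax(boot$draws[, , 1], boot$draws[, , 2])
  expect_equal(boot$boot_ci_lo, lo)
  expect_equal(boot$boot_ci_hi, hi)
})

test_that("a strong single-channel effect is reliable and null channels rarely are", {
  n_rep <- 25
  planted_ok <- 0L
  fp <- 0L; fp_total <- 0L
  for (r in seq_len(n_rep)) {
    set.seed(100 + r)
    n <- 16
    Xa <- matrix(rnorm(n * 11), n)
    Xb <- matrix(rnorm(n * 11), n)
    Xb[, 1] <- Xb[, 1] + 5  # 5 SD effect in channel 1 only
    tm <- make_tm_two_cond(Xa, Xb)
    fit <- mean_centered_pls(tm)
    boot <- pls_bootstrap(tm, fit, n_boot = 100, seed = 200 + r)
    planted_ok <- planted_ok + boot$reliable_mask[1, 1]
    fp <- fp + sum(boot$reliable_mask[2:11, 1])
    fp_total <- fp_total + 10L
  }
  expect_gte(planted_ok, n_rep - 1)
  expect_lt(fp / fp_total, 0.12)
  expect_gt(fp / fp_total, 0.0)  # the rule is not vacuously conservative
})

test_that("bootstrap input requirements are enforced", {
  tm <- rand_task_matrix(2)
  expect_error(pls_bootstrap(tm, n_boot = 1), "n_boot")
  # single subject per group is rejected
  Xa <- matrix(rnorm(2), 1)
  Xb <- matrix(rnorm(2), 1)
  tm1 <- make_tm_two_cond(Xa, Xb)
  expect_error(pls_bootstrap(tm1, n_boot = 10, seed = 1), "2 subjects")
})

test_that("degenerate draws are resampled, not summarised", {
  # with 2 subjects per group half the draws repeat one subject; they must
  # be redrawn rather than producing zero-variance cells
  Xa <- matrix(rnorm(8), 2)
  Xb <- matrix(rnorm(8), 2)
  tm <- make_tm_two_cond(Xa, Xb)
  boot <- pls_bootstrap(tm, n_boot = 30, seed = 5, retry_cap = 1000)
  expect_gt(boot$n_retries, 0)
  expect_false(any(is.na(boot$boot_se)))
})
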