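# Independent oracles and fixture builders used across the suite.  Every
# oracle is coded from the defining formula, independently of the package's
# implementation path.

# O(n^2) discrete Fourier transform periodogram of one tapered segment:
# one-sided spectral density, 2|X_k|^2 / (fs * sum(w^2)), DC and Nyquist
# not doubled.
oracle_periodogram <- function(x, w, fs) {
  n <- length(x)
  xw <- x * w
  nf <- n %/% 2 + 1
  p <- numeric(nf)
  for (k in seq_len(nf) - 1) {
    X <- sum(xw * exp(-2i * pi * k * (seq_len(n) - 1) / n))
    dbl <- if (k == 0 || (n %% 2 == 0 && k == n / 2)) 1 else 2
    p[k + 1] <- dbl * Mod(X)^2 / (fs * sum(w^2))
  }
  p
}

# Independent short-time average: same documented segmentation rule
# (hop = floor((n - wp)/(nw - 1))), periodogram per segment, averaged over
# trials.
oracle_tfr <- function(signals, fs, wp, nw) {
  if (is.matrix(signals)) signals <- array(signals, c(1, dim(signals)))
  n_trial <- dim(signals)[1]; n_chan <- dim(signals)[2]
  n_samp <- dim(signals)[3]
  hop <- (n_samp - wp) %/% (nw - 1)
  starts <- 1 + (seq_len(nw) - 1) * hop
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(wp) - 1) / (wp - 1)))
  nf <- wp %/% 2 + 1
  pow <- array(0, c(n_chan, nf, nw))
  for (tr in seq_len(n_trial)) for (ch in seq_len(n_chan)) for (s in seq_len(nw)) {
    seg <- signals[tr, ch, starts[s]:(starts[s] + wp - 1)]
    pow[ch, , s] <- pow[ch, , s] + oracle_periodogram(seg, w, fs)
  }
  pow / n_trial
}

# Brute-force saliences from the eigendecomposition of Mc' Mc.
oracle_eigen_saliences <- function(Mc) {
  e <- eigen(crossprod(Mc), symmetric = TRUE)
  list(d = sqrt(pmax(e$values, 0)), V = e$vectors)
}

# Exact permutation p-values for a single-group, two-condition design
# under the subject-respecting scheme: every permutation swaps (or not)
# each subject's condition labels, so the permutation space is the 2^n
# within-subject swap patterns, enumerated exhaustively.
oracle_exhaustive_perm_p <- function(Xa, Xb) {
  n <- nrow(Xa)
  sig <- function(swap) {
    A <- Xa; B <- Xb
    A[swap, ] <- Xb[swap, , drop = FALSE]
    B[swap, ] <- Xa[swap, , drop = FALSE]
    ma <- colMeans(A); mb <- colMeans(B)
    g <- (ma + mb) / 2
    svd(rbind(ma - g, mb - g), nu = 0, nv = 0)$d
  }
  obs <- sig(logical(n))
  exceed <- numeric(length(obs))
  for (mask in 0:(2^n - 1)) {
    swap <- as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L))
    exceed <- exceed + (sig(swap) >= obs - 1e-12)
  }
  exceed / 2^n
}

# Free-row-relabelling analogue: all assignments of rows to condition A.
oracle_exhaustive_perm_p_rows <- function(X, n_per_cond) {
  n <- nrow(X)
  stopifnot(n == 2 * n_per_cond)
  sig <- function(rows_a) {
    ma <- colMeans(X[rows_a, , drop = FALSE])
    mb <- colMeans(X[-rows_a, , drop = FALSE])
    g <- (ma + mb) / 2
    svd(rbind(ma - g, mb - g), nu = 0, nv = 0)$d
  }
  obs <- sig(seq_len(n_per_cond))
  combos <- utils::combn(n, n_per_cond)
  exceed <- numeric(length(obs))
  for (j in seq_len(ncol(combos)))
    exceed <- exceed + (sig(combos[, j]) >= obs - 1e-12)
  exceed / ncol(combos)
}

# Task matrix for one group, two conditions, from per-condition data
# matrices (subjects x columns), built through the package constructors.
make_tm_two_cond <- function(Xa, Xb, group = "g") {
  n <- nrow(Xa); p <- ncol(Xa)
  vals <- array(NA_real_, c(n, 2, p, 1))
  vals[, 1, , 1] <- Xa
  vals[, 2, , 1] <- Xb
  pt <- power_tensor(vals, sprintf("s%03d", seq_len(n)), c("a", "b"),
                     sprintf("c%02d", seq_len(p)), "x",
                     rep(group, n))
  build_task_matrix(pt, conditions = c("a", "b"))
}

# Random small task matrix: 2 groups x 2 conditions x n subjects per group,
# 2 channels x 3 bands = 6 columns.
rand_task_matrix <- function(seed, n_per_group = 3) {
  set.seed(seed)
  n <- 2 * n_per_group
  vals <- array(rnorm(n * 2 * 2 * 3), c(n, 2, 2, 3))
  pt <- power_tensor(vals, sprintf("s%02d", seq_len(n)), c("a", "b"),
                     c("c1", "c2"), c("theta", "alpha", "beta"),
                     rep(c("g1", "g2"), each = n_per_group))
  build_task_matrix(pt, conditions = c("a", "b"))
}

# Small simulation config used by several suites.
small_config <- function(...) {
  sim_config(n_per_group = 4, n_channels = 3, n_trials = 20,
             conditions = c("pre_stimulus", "delay"), ...)
}
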