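#' Short-time Fourier time-frequency decomposition
#'
#' Computes a trial-averaged time-frequency representation (TFR) of
#' virtual-channel signals with Hann-tapered overlapping segments, following
#' the convention of a fixed number of windows per trial: the hop between
#' segment starts is derived as
#' `floor((n_samples - window_points) / (n_windows - 1))`, so the segments
#' tile the trial uniformly regardless of sampling rate.
#'
#' Power is a one-sided spectral density, `2 |FFT(w x)|^2 / (fs * sum(w^2))`
#' (DC and Nyquist bins not doubled), averaged over segments at each time
#' step and over trials.
#'
#' @param signals numeric array `trial x channel x sample`, or a
#'   `channel x sample` matrix for a single trial.
#' @param fs sampling rate, Hz.
#' @param window_points samples per Hann segment (default 512).
#' @param n_windows number of overlapping segments per trial (default 200).
#' @param t0 time of the first sample, s (e.g. -2.5 for an epoch starting
#'   2.5 s before the first study display).
#' @return an object of class `tfr`: list with `power`
#'   (`channel x frequency x time`), `freq` (Hz), `time` (segment centres, s),
#'   and the decomposition parameters.
#' @seealso [band_window_power()], [window_contrast()]
#' @export
compute_tfr <- function(signals, fs, window_points = 512L, n_windows = 200L,
                        t0 = 0) {
  if (is.matrix(signals)) signals <- array(signals, c(1L, dim(signals)))
  stopifnot(is.array(signals), length(dim(signals)) == 3L)
  if (!is_number(fs) || fs <= 0) stop("fs must be a positive number")
  if (!is_count(window_points, 2L)) stop("window_points must be a count >= 2")
  if (!is_count(n_windows, 2L)) stop("n_windows must be a count >= 2")
  n_trial <- dim(signals)[1]; n_chan <- dim(signals)[2]; n_samp <- dim(signals)[3]
  if (n_samp < window_points)
    stop("trial (", n_samp, " samples) shorter than one window (",
         window_points, ")")

  hop <- (n_samp - window_points) %/% (n_windows - 1L)
  starts <- 1L + (seq_len(n_windows) - 1L) * hop
  w <- hann_window(window_points)
  scale <- 2 / (fs * sum(w^2))
  n_freq <- window_points %/% 2L + 1L
  freq <- (seq_len(n_freq) - 1L) * fs / window_points
  # DC always single-sided; Nyquist bin single-sided when window length even
  half <- rep(1, n_freq)
  half[1] <- 0.5
  if (window_points %% 2L == 0L) half[n_freq] <- 0.5

  pow <- array(0, c(n_chan, n_freq, n_windows))
  seg_idx <- outer(seq_len(window_points) - 1L, starts, `+`)  # sample x segment
  for (tr in seq_len(n_trial)) {
    for (ch in seq_len(n_chan)) {
      segs <- matrix(signals[tr, ch, ][seg_idx], nrow = window_points)
      ft <- stats::mvfft(segs * w)[seq_len(n_freq), , drop = FALSE]
      pow[ch, , ] <- pow[ch, , ] + (Mod(ft)^2 * half) * scale
    }
  }
  pow <- pow / n_trial
  structure(list(power = pow, freq = freq,
                 time = t0 + (starts - 1L + (window_points - 1) / 2) / fs,
                 fs = fs, window_points = as.integer(window_points),
                 n_windows = as.integer(n_windows), n_trials = n_trial),
            class = "tfr")
}

# Symmetric Hann taper, w[k] = 0.5 (1 - cos(2 pi k / (N-1))).
hann_window <- function(n) {
  k <- seq_len(n) - 1L
  0.5 * (1 - cos(2 * pi * k / (n - 1)))
}

#' @export
print.tfr <- function(x, ...) {
  cat(sprintf(
    "tfr: %d channel(s), %d frequency bins (%.2f-%.2f Hz), %d time steps (%.2f-%.2f s), %d trial(s)\n",
    dim(x$power)[1], length(x$freq), min(x$freq), max(x$freq),
    length(x$time), min(x$time), max(x$time), x$n_trials))
  invisible(x)
}

#' Mean band power in a task window
#'
#' Averages TFR power over the frequency bins of a band and the time bins of
#' a window.  A bin belongs to the band/window when its centre lies inside
#' the closed interval, which makes inclusion at shared band edges
#' (7/9/14/15 Hz) reproducible.
#'
#' @param tfr a [compute_tfr()] result.
#' @param band a [band_definition()].
#' @param window `c(t0, t1)` in seconds on the TFR time axis.
#' @return numeric vector of mean power, one value per channel.
#' @export
band_window_power <- function(tfr, band, window) {
  stopifnot(inherits(tfr, "tfr"), inherits(band, "band_definition"),
            is.numeric(window), length(window) == 2L, window[1] < window[2])
  fi <- which(tfr$freq >= band$f_lo & tfr$freq <= band$f_hi)
  ti <- which(tfr$time >= window[1] & tfr$time <= window[2])
  if (!length(fi)) stop("no frequency bins inside band '", band$name, "'")
  if (!length(ti)) stop("no time bins inside window [", window[1], ", ",
                        window[2], "] s")
  apply(tfr$power[, fi, ti, drop = FALSE], 1L, mean)
}

#' Window contrast of band power
#'
#' Elementwise difference `a - b` between two power slices with identical
#' axes; positive values mean a power increase in the task window relative
#' to its comparison window.
#'
#' @param power_a,power_b conformable numeric arrays (e.g. subject x channel
#'   x band slices of a power tensor) with identical dimnames.
#' @return array of differences with the shared axes.
#' @export
window_contrast <- function(power_a, power_b) {
  if (!identical(dim(power_a) %||% length(power_a),
                 dim(power_b) %||% length(power_b)) ||
      !identical(dimnames(power_a), dimnames(power_b)))
    stop("window_contrast: axis mismatch between the two slices")
  power_a - power_b
}
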