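#' Planted power effect
#'
#' Describes a group-by-phase effect planted in the synthetic power tensor:
#' the named conditions' cell means, at the given channels and bands, are
#' shifted by `magnitude` within-cell standard deviations (the within-cell
#' SD is `sqrt(noise_sd^2 + subject_sd^2)`), for one group or for both.
#'
#' @param channels channel indices or labels.
#' @param bands band names.
#' @param conditions condition (task-window) names the shift applies to.
#' @param magnitude signed effect size in within-cell SD units; negative
#'   values plant a power decrease (ERD-like).
#' @param group group label, or `NULL` for both groups.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(channels, bands, conditions, magnitude, group = NULL) {
  stopifnot(length(channels) >= 1L, length(bands) >= 1L,
            length(conditions) >= 1L, is_number(magnitude))
  structure(list(channels = channels, bands = bands, conditions = conditions,
                 magnitude = magnitude, group = group),
            class = "effect_spec")
}

#' Planted brain-behaviour coupling
#'
#' Couples a power contrast to response time through a shared standard-normal
#' latent factor per subject: the latent loads with weight
#' `strength * within-cell SD` on the named condition's power at the coupled
#' channels/bands, and on the subject's log response-time location with the
#' loading required to make the correlation between the mean coupled-channel
#' contrast (`condition - baseline`) and log RT equal `r` analytically.
#'
#' @param group group label the coupling is planted in.
#' @param channels,bands coupled channel indices/labels and band names.
#' @param condition task-window condition carrying the latent.
#' @param baseline comparison condition defining the contrast.
#' @param r target Pearson correlation between the mean coupled contrast and
#'   log RT; `|r| < 1`.  Positive `r` means larger contrast, slower responses.
#' @param strength latent loading on power, in within-cell SD units.
#' @return an object of class `coupling_spec`.
#' @export
coupling_spec <- function(group, channels, bands, condition,
                          baseline = "first_study", r, strength = 1) {
  stopifnot(is.character(group), length(group) == 1L,
            is_number(r), is_number(strength), strength > 0)
  if (abs(r) >= 1) stop("coupling r must satisfy |r| < 1")
  structure(list(group = group, channels = channels, bands = bands,
                 condition = condition, baseline = baseline,
                 r = r, strength = strength),
            class = "coupling_spec")
}

#' Behaviour model defaults
#'
#' Group-level behaviour parameters on the scales of the study: accuracy
#' mean/SD in percent, mean-correct-RT mean/SD in ms (subject-level
#' log-normal), hippocampal volume mean/SD in mm^3.
#'
#' @param groups group labels (first entry is the younger-adult-like group).
#' @return named list, one parameter list per group.
#' @export
default_behaviour_model <- function(groups = c("younger", "older")) {
  stopifnot(length(groups) == 2L)
  out <- list(
    list(accuracy_mean = 82.5, accuracy_sd = 9.2,
         rt_mean = 1543, rt_sd = 205,
         volume_mean = 7595.4, volume_sd = 940.4),
    list(accuracy_mean = 81.3, accuracy_sd = 10.7,
         rt_mean = 2042, rt_sd = 553,
         volume_mean = 7321.6, volume_sd = 812.9))
  stats::setNames(out, groups)
}

#' Simulation configuration
#'
#' Assembles and validates every parameter of the synthetic study: a
#' two-group, multi-phase design with 16 subjects per group, 90 virtual
#' channels, three frequency bands and 204 trials by default, plus planted
#' power effects and an optional brain-behaviour coupling.
#'
#' Power is generated on the natural-log scale as
#' `baseline(band) + planted effects + subject intercept + N(0, noise_sd)`,
#' so SD-unit effect magnitudes are scale-free; set `log_power = FALSE` to
#' exponentiate into linear power.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param groups two group labels.
#' @param n_channels number of virtual channels.
#' @param bands list of [band_definition()]s (non-overlapping).
#' @param timeline a [trial_timeline()].
#' @param window_variant passed to [analysis_windows()].
#' @param conditions task-window names generated in the tensor; default all
#'   windows of the timeline.
#' @param n_trials trials per subject.
#' @param effects list of [effect_spec()]s.
#' @param coupling a [coupling_spec()] or `NULL`.
#' @param behaviour_model per-group behaviour parameters, see
#'   [default_behaviour_model()].
#' @param noise_sd SD of the Gaussian log-power noise (> 0).
#' @param subject_sd SD of the per-subject log-power intercept.
#' @param baseline_log_power named per-band baseline log power; defaults to 1
#'   for every band.
#' @param log_power generate log power (default) or linear power.
#' @param sdlog_trial trial-level log-normal RT spread (log-ms scale).
#' @param p_fast fraction of trials drawn as fast guesses with RT uniform in
#'   `fast_range_ms`, making the RT > 1 s response-locked filter non-trivial.
#' @param fast_range_ms RT range of fast guesses, ms.
#' @param practice_ms planted practice effect: expected first-half minus
#'   last-half mean RT difference, ms.
#' @param channels channel labels; defaults to the bundled 90-region AAL
#'   parcellation names when `n_channels == 90`, else `ch001, ...`.
#' @param timecourse parameters for [simulate_timecourses()]: list with
#'   `fs`, `background_rms`, and `carriers` (list of
#'   `list(channels, band, freq = NULL, base_amp, gains)` where `gains` is a
#'   named per-phase amplitude multiplier over pre_stimulus/study/delay/test).
#' @param seed default seed used when the generator is called without one.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 16, groups = c("younger", "older"),
                       n_channels = 90, bands = band_set(),
                       timeline = trial_timeline(),
                       window_variant = "methods",
                       conditions = NULL, n_trials = 204,
                       effects = list(), coupling = NULL,
                       behaviour_model = default_behaviour_model(groups),
                       noise_sd = 1, subject_sd = 0.5,
                       baseline_log_power = NULL, log_power = TRUE,
                       sdlog_trial = 0.25, p_fast = 0.05,
                       fast_range_ms = c(300, 1000), practice_ms = 134,
                       channels = NULL, timecourse = NULL, seed = NULL) {
  if (!is_count(n_per_group, 2L)) stop("n_per_group must be a count >= 2")
  stopifnot(length(groups) == 2L, !anyDuplicated(groups))
  if (!is_count(n_channels, 1L)) stop("n_channels must be a positive count")
  if (!is_count(n_trials, 2L)) stop("n_trials must be a count >= 2")
  if (!is_number(noise_sd) || noise_sd <= 0) stop("noise_sd must be positive")
  if (!is_number(subject_sd) || subject_sd < 0) stop("subject_sd must be >= 0")
  stopifnot(is_number(sdlog_trial), sdlog_trial > 0,
            is_number(p_fast), p_fast >= 0, p_fast < 1,
            is_number(practice_ms))
  check_bands(bands)
  names(bands) <- vapply(bands, `[[`, "", "name")
  windows <- analysis_windows(timeline, window_variant)
  conditions <- conditions %||% names(windows)
  if (!all(conditions %in% names(windows)))
    stop("unknown condition(s): ",
         paste(setdiff(conditions, names(windows)), collapse = ", "))
  if (is.null(channels)) channels <- default_channel_labels(n_channels)
  stopifnot(length(channels) == n_channels, !anyDuplicated(channels))
  if (is.null(baseline_log_power))
    baseline_log_power <- stats::setNames(rep(1, length(bands)), names(bands))
  stopifnot(all(names(bands) %in% names(baseline_log_power)))
  for (g in groups) {
    bm <- behaviour_model[[g]]
    if (is.null(bm)) stop("behaviour_model missing group '", g, "'")
    for (f in c("accuracy_mean", "accuracy_sd", "rt_mean", "rt_sd",
                "volume_mean", "volume_sd"))
      if (!is_number(bm[[f]])) stop("behaviour_model$", g, "$", f, " invalid")
  }

  cfg <- structure(list(
    n_per_group = as.integer(n_per_group), groups = groups,
    n_channels = as.integer(n_channels), bands = bands,
    timeline = timeline, window_variant = window_variant,
    windows = windows, conditions = conditions,
    n_trials = as.integer(n_trials), effects = effects, coupling = coupling,
    behaviour_model = behaviour_model, noise_sd = noise_sd,
    subject_sd = subject_sd, baseline_log_power = baseline_log_power,
    log_power = isTRUE(log_power), sdlog_trial = sdlog_trial,
    p_fast = p_fast, fast_range_ms = fast_range_ms,
    practice_ms = practice_ms, channels = channels,
    timecourse = timecourse, seed = seed), class = "sim_config")

  cfg$effects <- lapply(effects, resolve_effect, cfg = cfg)
  if (!is.null(coupling)) cfg$coupling <- resolve_coupling(coupling, cfg)
  cfg
}

# Within-cell SD across subjects (subject intercept + observation noise):
# the unit in which planted magnitudes and coupling strengths are expressed.
cell_sd <- function(cfg) sqrt(cfg$noise_sd^2 + cfg$subject_sd^2)

resolve_effect <- function(e, cfg) {
  if (!inherits(e, "effect_spec")) stop("effects must be effect_spec objects")
  e$channels <- resolve_channels(e$channels, cfg)
  if (!all(e$bands %in% names(cfg$bands)))
    stop("effect references unknown band(s): ",
         paste(setdiff(e$bands, names(cfg$bands)), collapse = ", "))
  if (!all(e$conditions %in% cfg$conditions))
    stop("effect references unknown condition(s): ",
         paste(setdiff(e$conditions, cfg$conditions), collapse = ", "))
  if (!is.null(e$group) && !e$group %in% cfg$groups)
    stop("effect references unknown group '", e$group, "'")
  e
}

resolve_coupling <- function(cp, cfg) {
  if (!inherits(cp, "coupling_spec")) stop("coupling must be a coupling_spec")
  cp$channels <- resolve_channels(cp$channels, cfg)
  stopifnot(all(cp$bands %in% names(cfg$bands)),
            cp$condition %in% cfg$conditions,
            cp$baseline %in% cfg$conditions,
            cp$group %in% cfg$groups)
  # Attenuation of the latent by observation noise: the mean contrast over
  # the K coupled columns has variance (strength*s)^2 + 2*noise_sd^2/K, so
  # the RT-side loading must be r / c0 with c0 the power-side correlation.
  K <- length(cp$channels) * length(cp$bands)
  s <- cell_sd(cfg)
  c0 <- cp$strength * s / sqrt((cp$strength * s)^2 + 2 * cfg$noise_sd^2 / K)
  cp$rt_loading <- cp$r / c0
  if (abs(cp$rt_loading) >= 1)
    stop("coupling r = ", cp$r, " unattainable: increase strength or the ",
         "number of coupled channels (attainable |r| < ", round(c0, 3), ")")
  cp
}

resolve_channels <- function(ch, cfg) {
  if (is.numeric(ch)) {
    if (!all(ch >= 1 & ch <= cfg$n_channels & ch == round(ch)))
      stop("channel index outside 1..", cfg$n_channels)
    return(as.integer(ch))
  }
  idx <- match(ch, cfg$channels)
  if (anyNA(idx)) stop("unknown channel label(s): ",
                       paste(ch[is.na(idx)], collapse = ", "))
  idx
}

default_channel_labels <- function(n) {
  if (n == 90L) {
    meta <- aal90_channels()
    return(meta$channel)
  }
  sprintf("ch%03d", seq_len(n))
}

#' Bundled 90-region channel metadata
#'
#' Region labels of the 90 cerebral AAL parcels (cerebellum excluded) with
#' approximate MNI centroid coordinates.  Coordinates are metadata for
#' reporting only and never enter any computation.
#'
#' @return data.frame with columns channel, mni_x, mni_y, mni_z.
#' @export
aal90_channels <- function() {
  path <- system.file("extdata", "aal90_channels.tsv", package = "oscpls",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", rep("numeric", 3)))
}

# ---------------------------------------------------------------------------
# subject-level latent structure shared by the power and trial generators

make_subjects <- function(cfg, seed) {
  withr::with_seed(derive_seed(seed, "subjects"), {
    n <- cfg$n_per_group
    out <- NULL
    for (g in cfg$groups) {
      bm <- cfg$behaviour_model[[g]]
      z <- stats::rnorm(n)
      # subject-level mean correct RT ~ lognormal(rt_mean, rt_sd) across
      # subjects; the latent z loads on log RT with weight rt_loading when a
      # coupling targets this group.
      sdlog_s <- sqrt(log(1 + (bm$rt_sd / bm$rt_mean)^2))
      meanlog_s <- log(bm$rt_mean) - sdlog_s^2 / 2
      lam <- if (!is.null(cfg$coupling) && cfg$coupling$group == g)
        cfg$coupling$rt_loading else 0
      eps <- stats::rnorm(n)
      lrt_loc <- meanlog_s - cfg$sdlog_trial^2 / 2 +
        sdlog_s * (lam * z + sqrt(1 - lam^2) * eps)
      p_acc <- pmin(0.999, pmax(0.05,
        stats::rnorm(n, bm$accuracy_mean / 100, bm$accuracy_sd / 100)))
      vol <- stats::rnorm(n, bm$volume_mean, bm$volume_sd)
      out <- rbind(out, data.frame(
        subject = sprintf("%s_%02d", g, seq_len(n)), group = g,
        hipp_volume_mm3 = vol, z = z, p_acc = p_acc, lrt_loc = lrt_loc,
        u = stats::rnorm(n, 0, cfg$subject_sd),
        stringsAsFactors = FALSE))
    }
    out
  })
}

# Expected (noise-free, latent-free) cell-mean log power per group:
# array condition x channel x band, baseline plus planted effects.
expected_cell_means <- function(cfg) {
  dims <- c(length(cfg$conditions), cfg$n_channels, length(cfg$bands))
  dn <- list(condition = cfg$conditions, channel = cfg$channels,
             band = names(cfg$bands))
  s <- cell_sd(cfg)
  out <- list()
  for (g in cfg$groups) {
    E <- array(0, dims, dimnames = dn)
    for (b in names(cfg$bands)) E[, , b] <- cfg$baseline_log_power[[b]]
    for (e in cfg$effects) {
      if (!is.null(e$group) && e$group != g) next
      E[e$conditions, e$channels, e$bands] <-
        E[e$conditions, e$channels, e$bands] + e$magnitude * s
    }
    out[[g]] <- E
  }
  out
}

#' Generate a synthetic power dataset
#'
#' Draws the full study: a [power_tensor()] of per-subject, per-window band
#' power with planted effects, per-trial behaviour, subject metadata
#' (hippocampal volumes), and a ground-truth record of everything planted.
#'
#' Log power is `cell mean + subject intercept + coupling latent + N(0,
#' noise_sd)`; response times are log-normal per trial around a subject
#' location that shares a standard-normal latent with the coupled power
#' contrast, yielding the configured power-RT correlation.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical `(config, seed)` pairs give
#'   bit-identical output.
#' @param include_trials set `FALSE` to skip trial-level behaviour (faster
#'   for replicate simulations that only need the tensor).
#' @return an object of class `sim_dataset`: list with elements `power`,
#'   `subjects`, `trials`, `ground_truth`, `config`, `seed`.
#' @examples
#' cfg <- sim_config(n_per_group = 4, n_channels = 6,
#'                   conditions = c("pre_stimulus", "delay"))
#' ds <- simulate_power_dataset(cfg, seed = 1)
#' dim(ds$power$values)
#' @export
simulate_power_dataset <- function(config, seed = config$seed,
                                   include_trials = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) stop("a seed is required (argument or config$seed)")
  subj <- make_subjects(config, seed)
  E <- expected_cell_means(config)
  nC <- length(config$conditions); nCh <- config$n_channels
  nB <- length(config$bands); nS <- nrow(subj)
  s <- cell_sd(config)
  cp <- config$coupling

  vals <- withr::with_seed(derive_seed(seed, "power"), {
    v <- array(NA_real_, c(nS, nC, nCh, nB))
    for (i in seq_len(nS)) {
      cell <- E[[subj$group[i]]] + subj$u[i]
      if (!is.null(cp) && cp$group == subj$group[i])
        cell[cp$condition, cp$channels, cp$bands] <-
          cell[cp$condition, cp$channels, cp$bands] +
          cp$strength * s * subj$z[i]
      v[i, , , ] <- cell + stats::rnorm(nC * nCh * nB, 0, config$noise_sd)
    }
    v
  })
  if (!config$log_power) vals <- exp(vals)

  power <- power_tensor(vals, subj$subject, config$conditions,
                        config$channels, names(config$bands), subj$group,
                        log_power = config$log_power)
  trials <- if (include_trials) make_trials(config, subj, seed) else NULL
  gt <- list(effects = config$effects, coupling = cp, cell_sd = s,
             expected_cell_means = E,
             latent = stats::setNames(subj$z, subj$subject),
             p_acc = stats::setNames(subj$p_acc, subj$subject),
             rt_location = stats::setNames(subj$lrt_loc, subj$subject))
  structure(list(power = power,
                 subjects = subj[, c("subject", "group", "hipp_volume_mm3")],
                 trials = trials, ground_truth = gt, config = config,
                 seed = seed),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset (seed ", x$seed, ")\n", sep = "")
  print(x$power)
  cat(length(x$config$effects), "planted effect(s); coupling:",
      if (is.null(x$config$coupling)) "none" else
        sprintf("%s, r = %.2f", x$config$coupling$group, x$config$coupling$r),
      "\n")
  invisible(x)
}

#' Generate trial-level behaviour only
#'
#' Same subjects and trial stream as [simulate_power_dataset()] under the
#' same seed, without drawing the power tensor.
#'
#' @inheritParams simulate_power_dataset
#' @return data.frame of trials: subject, group, trial_index, condition,
#'   response, rt_ms.
#' @export
simulate_trials <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) stop("a seed is required")
  make_trials(config, make_subjects(config, seed), seed)
}

make_trials <- function(cfg, subj, seed) {
  withr::with_seed(derive_seed(seed, "trials"), {
    n <- cfg$n_trials
    half <- n / 2
    # practice effect: linear drift whose first-half-minus-last-half mean
    # difference equals practice_ms
    drift <- cfg$practice_ms * ((n + 1) / 2 - seq_len(n)) / half
    out <- vector("list", nrow(subj))
    for (i in seq_len(nrow(subj))) {
      cond <- sample(rep(c("intact", "manipulated"), length.out = n))
      correct <- stats::rbinom(n, 1L, subj$p_acc[i]) == 1L
      rt <- stats::rlnorm(n, subj$lrt_loc[i], cfg$sdlog_trial)
      fast <- stats::runif(n) < cfg$p_fast
      rt[fast] <- stats::runif(sum(fast), cfg$fast_range_ms[1],
                               cfg$fast_range_ms[2])
      rt <- pmin(4000, pmax(250, rt + drift))
      out[[i]] <- data.frame(
        subject = subj$subject[i], group = subj$group[i],
        trial_index = seq_len(n), condition = cond,
        response = ifelse(correct, "correct", "incorrect"),
        rt_ms = rt, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

# ---------------------------------------------------------------------------
# raw time-course generator: 1/f background plus phase-gated band carriers

#' Generate trial time courses
#'
#' Simulates raw virtual-channel signals as a 1/f (pink) background plus
#' band-limited sinusoidal carriers whose amplitude is piecewise constant
#' over the task phases (pre-stimulus, study, delay, test), so the spectral
#' stage can be exercised end-to-end against an analytic amplitude^2/2 power
#' oracle.
#'
#' @param config a [sim_config()] whose `timecourse` field sets `fs` (Hz),
#'   `background_rms`, and `carriers`.
#' @param seed integer seed.
#' @param n_trials number of trials to draw.
#' @param n_channels number of channels (carriers reference these indices).
#' @return list with `signals` (`trial x channel x sample`), `fs`, `time`
#'   (s, stimulus-referenced), class `sim_timecourses`.
#' @export
simulate_timecourses <- function(config, seed = config$seed, n_trials = 20,
                                 n_channels = 2) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) stop("a seed is required")
  tc <- config$timecourse %||% list()
  fs <- tc$fs %||% 250
  background_rms <- tc$background_rms %||% 0.2
  carriers <- tc$carriers %||% list()
  stopifnot(is_number(fs), fs > 0)
  for (ca in carriers) {
    b <- config$bands[[ca$band]]
    if (is.null(b)) stop("carrier references unknown band '", ca$band, "'")
    f <- ca$freq %||% ((b$f_lo + b$f_hi) / 2)
    if (f >= fs / 2) stop("carrier frequency ", f, " Hz at or above Nyquist")
  }
  ep <- config$timeline$epoch
  n_samp <- round((ep[2] - ep[1]) * fs)
  tt <- ep[1] + (seq_len(n_samp) - 1) / fs
  phase_lab <- phase_of(tt, config$timeline)

  withr::with_seed(derive_seed(seed, "timecourses"), {
    sig <- array(0, c(n_trials, n_channels, n_samp))
    for (tr in seq_len(n_trials)) for (ch in seq_len(n_channels)) {
      x <- if (background_rms > 0) pink_noise(n_samp, background_rms) else
        numeric(n_samp)
      for (ca in carriers) {
        if (!ch %in% ca$channels) next
        b <- config$bands[[ca$band]]
        f <- ca$freq %||% ((b$f_lo + b$f_hi) / 2)
        amp <- (ca$base_amp %||% 1) *
          unname(unlist(ca$gains)[phase_lab])
        amp[is.na(amp)] <- 0
        x <- x + amp * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
      }
      sig[tr, ch, ] <- x
    }
    structure(list(signals = sig, fs = fs, time = tt), class = "sim_timecourses")
  })
}

# 1/f-power background: white spectrum shaped by 1/sqrt(f), zero DC,
# rescaled to the requested rms.
pink_noise <- function(n, rms) {
  X <- stats::fft(stats::rnorm(n))
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)
  sc <- ifelse(f > 0, 1 / sqrt(f), 0)
  x <- Re(stats::fft(X * sc, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

#' Write ground truth as JSON
#'
#' @param ground_truth the `ground_truth` element of a
#'   [simulate_power_dataset()] result.
#' @param path output path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- ground_truth
  gt$expected_cell_means <- lapply(gt$expected_cell_means, function(a) {
    df <- as.data.frame.table(a, responseName = "mean_log_power",
                              stringsAsFactors = FALSE)
    names(df)[1:3] <- c("condition", "channel", "band")
    df
  })
  gt$effects <- lapply(gt$effects, unclass)
  if (!is.null(gt$coupling)) gt$coupling <- unclass(gt$coupling)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
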