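#' Trial timeline of the visuospatial memory task
#'
#' One trial presents three study objects sequentially (3 s each, starting at
#' 0, 3 and 6 s), a 2 s mask/delay (9-11 s) and a 4 s test display (11-15 s).
#' The analysed epoch runs from -2.5 s before the first study display to the
#' end of the test phase.
#'
#' @param study_onsets onsets of the three study displays, s.
#' @param delay_onset,test_onset,trial_end phase boundaries, s.
#' @param epoch analysed epoch `c(start, end)`, s relative to first study onset.
#' @return an object of class `trial_timeline`.
#' @export
trial_timeline <- function(study_onsets = c(0, 3, 6), delay_onset = 9,
                           test_onset = 11, trial_end = 15,
                           epoch = c(-2.5, 15)) {
  stopifnot(length(study_onsets) == 3L, all(diff(study_onsets) > 0),
            is_number(delay_onset), is_number(test_onset), is_number(trial_end),
            length(epoch) == 2L, epoch[1] < epoch[2])
  if (!(max(study_onsets) < delay_onset && delay_onset < test_onset &&
        test_onset < trial_end))
    stop("phase boundaries must be ordered: study < delay < test < end")
  structure(list(study_onsets = study_onsets, delay_onset = delay_onset,
                 test_onset = test_onset, trial_end = trial_end, epoch = epoch),
            class = "trial_timeline")
}

#' Analysis windows for band-power extraction
#'
#' Returns the named task windows over which band power is averaged.  Each
#' window is `list(window = c(t0, t1), reference = "stimulus"|"response")`;
#' stimulus-referenced times are seconds relative to the first study onset,
#' response-referenced times are relative to the button press.
#'
#' Windows: `pre_stimulus` (-0.75 to 0 s before the first study display, with
#' a -0.25 to 0 s variant), `first_study` (0.25-2.5 s), `first_study_short`
#' (0.25-1.25 s, the baseline for the response-locked analysis), `delay`
#' (0.75-1.5 s after delay onset, with a 0.25-1.5 s variant), `test`
#' (0.25-2.5 s after test onset) and `response` (-1.0 to 0 s before the
#' button press).  Windows deliberately skip the first ~250 ms of each phase
#' so that sustained power changes, not the initial evoked response, are
#' analysed.
#'
#' @param timeline a [trial_timeline()].
#' @param variant `"methods"` (default) or `"results"`; the latter uses the
#'   narrower pre-stimulus (-0.25-0 s) and wider delay (0.25-1.5 s) windows.
#' @return named list of window descriptors.
#' @export
analysis_windows <- function(timeline = trial_timeline(),
                             variant = c("methods", "results")) {
  variant <- match.arg(variant)
  stopifnot(inherits(timeline, "trial_timeline"))
  pre  <- if (variant == "methods") c(-0.75, 0) else c(-0.25, 0)
  dly  <- if (variant == "methods") c(0.75, 1.5) else c(0.25, 1.5)
  s1   <- timeline$study_onsets[1]
  win <- function(w, ref = "stimulus") list(window = w, reference = ref)
  w <- list(
    pre_stimulus      = win(s1 + pre),
    first_study       = win(s1 + c(0.25, 2.5)),
    first_study_short = win(s1 + c(0.25, 1.25)),
    delay             = win(timeline$delay_onset + dly),
    test              = win(timeline$test_onset + c(0.25, 2.5)),
    response          = win(c(-1.0, 0), ref = "response"))
  for (nm in names(w)) {
    ww <- w[[nm]]$window
    if (ww[1] >= ww[2]) stop("window '", nm, "' has start >= end")
    if (w[[nm]]$reference == "stimulus" &&
        (ww[1] < timeline$epoch[1] || ww[2] > timeline$epoch[2]))
      stop("window '", nm, "' lies outside the analysed epoch")
  }
  w
}

# Phase label for a stimulus-referenced time point; used by the time-course
# simulator to apply phase-wise carrier gains.
phase_of <- function(t, timeline) {
  p <- character(length(t))
  p[t < timeline$study_onsets[1]] <- "pre_stimulus"
  p[t >= timeline$study_onsets[1] & t < timeline$delay_onset] <- "study"
  p[t >= timeline$delay_onset & t < timeline$test_onset] <- "delay"
  p[t >= timeline$test_onset] <- "test"
  p
}
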