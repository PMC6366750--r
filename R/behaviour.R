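#' Per-subject behavioural summaries
#'
#' Accuracy is `100 * #correct / #trials` over all trials of the subject
#' (non-responses count as incorrect in this forced-choice design); response
#' time is averaged over correct trials only.
#'
#' @param trials data.frame with columns subject, group, trial_index,
#'   condition, response (`"correct"`, `"incorrect"` or `"none"`), rt_ms.
#' @return data.frame with one row per subject: subject, group, n_trials,
#'   n_correct, accuracy_pct, mean_correct_rt_ms (NA when no trial is
#'   correct), and a logical `no_correct_trials` flag.
#' @export
summarize_subjects <- function(trials) {
  check_trials(trials)
  ids <- unique(trials$subject)
  out <- lapply(ids, function(s) {
    tr <- trials[trials$subject == s, ]
    ok <- tr$response == "correct"
    data.frame(subject = s, group = tr$group[1],
               n_trials = nrow(tr), n_correct = sum(ok),
               accuracy_pct = 100 * sum(ok) / nrow(tr),
               mean_correct_rt_ms = if (any(ok)) mean(tr$rt_ms[ok]) else
                 NA_real_,
               no_correct_trials = !any(ok),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

check_trials <- function(trials) {
  need <- c("subject", "group", "trial_index", "condition", "response",
            "rt_ms")
  if (!all(need %in% names(trials)))
    stop("trials must have columns: ", paste(need, collapse = ", "))
  if (nrow(trials) < 1L) stop("need at least one trial")
  dup <- stats::aggregate(trial_index ~ subject, trials,
                          function(v) anyDuplicated(v) > 0L)
  if (any(dup$trial_index))
    stop("duplicate trial_index within subject(s): ",
         paste(dup$subject[dup$trial_index], collapse = ", "))
  invisible(trials)
}

#' Behaviour table (accuracy, RT, hippocampal volume)
#'
#' Joins per-subject behavioural summaries with subject metadata into the
#' table the behavioural PLS consumes.
#'
#' @param trials trial-level data.frame (see [summarize_subjects()]).
#' @param subjects data.frame with columns subject and hipp_volume_mm3
#'   (e.g. the `subjects` element of a [simulate_power_dataset()] result).
#' @return data.frame: subject, group, accuracy_pct, mean_rt_ms,
#'   hipp_volume_mm3.
#' @export
behaviour_table <- function(trials, subjects) {
  s <- summarize_subjects(trials)
  vol <- subjects$hipp_volume_mm3[match(s$subject, subjects$subject)]
  data.frame(subject = s$subject, group = s$group,
             accuracy_pct = s$accuracy_pct,
             mean_rt_ms = s$mean_correct_rt_ms,
             hipp_volume_mm3 = vol, stringsAsFactors = FALSE)
}

#' Read and write behaviour tables
#'
#' Tab-separated text with columns subject, group, accuracy_pct, mean_rt_ms,
#' hipp_volume_mm3.
#'
#' @param x behaviour table data.frame.
#' @param path file path.
#' @export
write_behaviour_table <- function(x, path) {
  for (cc in names(x))
    if (is.double(x[[cc]])) x[[cc]] <- sprintf("%.17g", x[[cc]])
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behaviour_table
#' @export
read_behaviour_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("subject", "group", "accuracy_pct", "mean_rt_ms",
            "hipp_volume_mm3")
  if (!all(need %in% names(df)))
    stop("behaviour table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Pooled two-sample t statistic from summary statistics
#'
#' Pooled-variance two-sample t (df = n1 + n2 - 2) computed directly from
#' group means, SDs and sizes, as used for the group comparisons of
#' accuracy, response time and hippocampal volume.  A Welch variant is
#' available by flag.
#'
#' @param m1,sd1,n1,m2,sd2,n2 group summary statistics.
#' @param welch use the Welch unequal-variance statistic and
#'   Satterthwaite df.
#' @return list with `t`, `df`, `p` (two-sided).  When both SDs are zero,
#'   `t` is 0 for equal means and `Inf` (flagged via `degenerate = TRUE`)
#'   otherwise.
#' @examples
#' pooled_t(1543, 205, 16, 2042, 553, 16)  # |t| ~ 3.38, df 30
#' @export
pooled_t <- function(m1, sd1, n1, m2, sd2, n2, welch = FALSE) {
  stopifnot(is_number(m1), is_number(m2), is_number(sd1), is_number(sd2),
            sd1 >= 0, sd2 >= 0, is_count(n1, 2L), is_count(n2, 2L))
  if (sd1 == 0 && sd2 == 0) {
    t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
    return(list(t = t, df = n1 + n2 - 2, p = if (m1 == m2) 1 else 0,
                degenerate = TRUE))
  }
  if (welch) {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    t <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Split-half response times (fatigue/practice check)
#'
#' Mean correct-trial RT over the first versus the last half of the trial
#' sequence, split strictly by trial index.
#'
#' @param trials trial-level data.frame for any number of subjects.
#' @param n_expected expected trials per subject (default 204); when a
#'   subject has fewer, the split falls at half the available trials and a
#'   warning is issued.
#' @return data.frame per subject: subject, group, rt_first_half,
#'   rt_second_half (ms, correct trials only).
#' @export
split_half_rt <- function(trials, n_expected = 204L) {
  check_trials(trials)
  ids <- unique(trials$subject)
  out <- lapply(ids, function(s) {
    tr <- trials[trials$subject == s, ]
    cut <- n_expected / 2
    if (nrow(tr) < n_expected) {
      warning("subject ", s, " has ", nrow(tr), " < ", n_expected,
              " trials; splitting proportionally")
      cut <- nrow(tr) / 2
    }
    first <- tr$response == "correct" & tr$trial_index <= cut
    last <- tr$response == "correct" & tr$trial_index > cut
    data.frame(subject = s, group = tr$group[1],
               rt_first_half = mean(tr$rt_ms[first]),
               rt_second_half = mean(tr$rt_ms[last]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Trial selection for the response-locked analysis
#'
#' Keeps correct trials in which the response came strictly more than 1 s
#' after test-stimulus onset, so the pre-response window cannot reach back
#' into the delay period.
#'
#' @param trials trial-level data.frame.
#' @param min_rt_ms inclusion threshold, ms (strict inequality).
#' @return list with `trials` (the retained subset) and `counts`
#'   (data.frame subject, group, n_retained).
#' @export
select_response_locked <- function(trials, min_rt_ms = 1000) {
  check_trials(trials)
  keep <- trials$response == "correct" & trials$rt_ms > min_rt_ms
  sel <- trials[keep, , drop = FALSE]
  ids <- unique(trials$subject)
  counts <- data.frame(
    subject = ids,
    group = trials$group[match(ids, trials$subject)],
    n_retained = as.integer(table(factor(sel$subject, levels = ids))),
    stringsAsFactors = FALSE)
  list(trials = sel, counts = counts)
}

#' Outlier flag at k standard deviations
#'
#' Flags values lying strictly more than `k` SDs from the mean, with mean
#' and SD computed over all supplied values (the candidate included).  With
#' zero SD nothing is flagged.  Note the rule is insensitive at tiny n: a
#' single extreme value inflates the SD enough to shield itself.
#'
#' @param values numeric vector (>= 3 values).
#' @param k threshold in SD units (default 2.5).
#' @return logical mask, `TRUE` where `|x - mean| > k * SD`.
#' @export
outlier_flag <- function(values, k = 2.5) {
  stopifnot(is.numeric(values), length(values) >= 3L, is_number(k), k > 0)
  s <- stats::sd(values)
  if (s == 0) return(rep(FALSE, length(values)))
  abs(values - mean(values)) > k * s
}

#' Group summary statistics with pooled t tests
#'
#' The analogue of the study's behaviour table: per-group mean and SD of
#' hippocampal volume, accuracy and mean correct RT, with the pooled
#' two-sample t for each measure.
#'
#' @param behaviour a [behaviour_table()] (or equivalent data.frame).
#' @return data.frame, one row per measure: group means/SDs, t, df, p.
#' @export
behaviour_group_stats <- function(behaviour) {
  groups <- unique(behaviour$group)
  stopifnot(length(groups) == 2L)
  measures <- c(hipp_volume_mm3 = "hipp_volume_mm3",
                accuracy_pct = "accuracy_pct", mean_rt_ms = "mean_rt_ms")
  out <- lapply(names(measures), function(m) {
    v1 <- behaviour[[m]][behaviour$group == groups[1]]
    v2 <- behaviour[[m]][behaviour$group == groups[2]]
    v1 <- v1[is.finite(v1)]; v2 <- v2[is.finite(v2)]
    tt <- pooled_t(mean(v1), stats::sd(v1), length(v1),
                   mean(v2), stats::sd(v2), length(v2))
    res <- data.frame(measure = m,
                      mean_1 = mean(v1), sd_1 = stats::sd(v1),
                      mean_2 = mean(v2), sd_2 = stats::sd(v2),
                      t = tt$t, df = tt$df, p = tt$p,
                      stringsAsFactors = FALSE)
    names(res)[2:5] <- paste(c("mean", "sd"), rep(groups, each = 2),
                             sep = "_")
    res
  })
  res <- do.call(rbind, out)
  attr(res, "groups") <- groups
  res
}
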