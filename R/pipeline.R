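#' Analysis plan
#'
#' Names the contrasts to run and the inference settings.  The standard
#' contrasts mirror the study analyses: `delay` (delay window minus
#' pre-stimulus), `test_stimulus_locked` (test window minus first study
#' display, alternative baseline pre-stimulus) and `response_locked`
#' (pre-response window minus the short first-study window, alternative
#' baseline pre-stimulus).
#'
#' @param contrasts subset of the three standard contrast names.
#' @param test_baseline baseline for the stimulus-locked test contrast.
#' @param response_baseline baseline for the response-locked contrast.
#' @param groups `"both"` or a single group label.
#' @param measures behaviour measures entering the behavioural PLS.
#' @param n_perm,n_boot resampling sizes.
#' @param alpha significance level in (0, 1).
#' @param centering,scheme passed to the task PLS.
#' @return an object of class `analysis_plan`.
#' @export
analysis_plan <- function(contrasts = c("delay", "test_stimulus_locked",
                                        "response_locked"),
                          test_baseline = c("first_study", "pre_stimulus"),
                          response_baseline = c("first_study_short",
                                                "pre_stimulus"),
                          groups = "both",
                          measures = c("accuracy_pct", "mean_rt_ms",
                                       "hipp_volume_mm3"),
                          n_perm = 1000, n_boot = 1000, alpha = 0.05,
                          centering = "grand", scheme = "subjects") {
  test_baseline <- match.arg(test_baseline)
  response_baseline <- match.arg(response_baseline)
  known <- c("delay", "test_stimulus_locked", "response_locked")
  if (!all(contrasts %in% known))
    stop("unknown contrast(s): ",
         paste(setdiff(contrasts, known), collapse = ", "))
  stopifnot(is_number(alpha), alpha > 0, alpha < 1,
            is_count(n_perm, 1L), is_count(n_boot, 2L))
  defs <- list(
    delay = list(task = "delay", baseline = "pre_stimulus"),
    test_stimulus_locked = list(task = "test", baseline = test_baseline),
    response_locked = list(task = "response", baseline = response_baseline))
  structure(list(contrasts = defs[contrasts], groups = groups,
                 measures = measures, n_perm = as.integer(n_perm),
                 n_boot = as.integer(n_boot), alpha = alpha,
                 centering = centering, scheme = scheme),
            class = "analysis_plan")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> task PLS -> behavioural PLS ->
#' behaviour statistics for every contrast of the plan, for the pooled
#' groups and for each group separately, deterministically under the given
#' seed.  Subjects whose mean correct RT is flagged as a within-group
#' outlier (2.5 SD rule) are excluded from the response-locked behavioural
#' PLS only, mirroring the study's exclusion rule.
#'
#' @param config a [sim_config()].
#' @param plan an [analysis_plan()].
#' @param seed integer seed controlling every stochastic stage.
#' @param dataset optionally a pre-built [simulate_power_dataset()] result
#'   (e.g. loaded from disk); simulated from `config` when omitted.
#' @param quiet suppress per-stage log lines.
#' @return an object of class `run_report` (see [report_summary()]).
#' @export
run_pipeline <- function(config, plan = analysis_plan(), seed,
                         dataset = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(plan, "analysis_plan"))
  log_line <- function(...) if (!quiet) message("[oscpls] ", sprintf(...))
  t_start <- proc.time()[["elapsed"]]

  dataset <- dataset %||% simulate_power_dataset(config, seed)
  pw <- dataset$power
  log_line("simulate: %d subjects x %d conditions x %d channels x %d bands (seed %d)",
           dim(pw$values)[1], dim(pw$values)[2], dim(pw$values)[3],
           dim(pw$values)[4], seed)

  behaviour <- behaviour_table(dataset$trials, dataset$subjects)
  stats_tbl <- behaviour_group_stats(behaviour)
  outliers <- behaviour
  outliers$accuracy_outlier <- FALSE
  outliers$rt_outlier <- FALSE
  for (g in unique(behaviour$group)) {
    rows <- behaviour$group == g
    outliers$accuracy_outlier[rows] <- outlier_flag(behaviour$accuracy_pct[rows])
    outliers$rt_outlier[rows] <- outlier_flag(behaviour$mean_rt_ms[rows])
  }
  rl_counts <- select_response_locked(dataset$trials)$counts
  log_line("behaviour: %d subjects summarised, %d RT outlier(s)",
           nrow(behaviour), sum(outliers$rt_outlier))

  groups <- if (identical(plan$groups, "both")) unique(unname(pw$group)) else
    plan$groups
  contrast_results <- list()
  for (nm in names(plan$contrasts)) {
    cdef <- plan$contrasts[[nm]]
    conds <- c(cdef$baseline, cdef$task)
    if (!all(conds %in% dimnames(pw$values)$condition))
      stop("contrast '", nm, "': condition(s) missing from tensor: ",
           paste(setdiff(conds, dimnames(pw$values)$condition),
                 collapse = ", "))
    cseed <- derive_seed(seed, nm)

    tm <- build_task_matrix(pw, conditions = conds, groups = groups)
    task <- task_pls(tm, n_perm = plan$n_perm, n_boot = plan$n_boot,
                     seed = cseed, centering = plan$centering,
                     scheme = plan$scheme, alpha = plan$alpha)
    by_group <- list()
    if (length(groups) > 1L) for (g in groups) {
      tg <- build_task_matrix(pw, conditions = conds, groups = g)
      by_group[[g]] <- task_pls(tg, n_perm = plan$n_perm,
                                n_boot = plan$n_boot,
                                seed = derive_seed(cseed, g),
                                centering = plan$centering,
                                scheme = plan$scheme, alpha = plan$alpha)
    }

    brain <- contrast_matrix(pw, cdef$task, cdef$baseline)
    behav <- behaviour
    if (nm == "response_locked") {
      drop <- outliers$subject[outliers$rt_outlier]
      if (length(drop)) {
        brain <- brain[!rownames(brain) %in% drop, , drop = FALSE]
        behav <- behav[!behav$subject %in% drop, , drop = FALSE]
        log_line("%s: excluded %d RT outlier(s) from behavioural PLS",
                 nm, length(drop))
      }
    }
    bp <- behavioural_pls(brain, behav, plan$measures,
                          group = pw$group,
                          n_perm = plan$n_perm, n_boot = plan$n_boot,
                          seed = derive_seed(cseed, "behav"),
                          alpha = plan$alpha)
    log_line("%s: task LV1 p = %.3g (%.1f%%), behavioural LV1 p = %.3g",
             nm, task$perm_p[1], task$crossblock_pct[1], bp$perm_p[1])
    contrast_results[[nm]] <- list(definition = cdef, task = task,
                                   task_by_group = by_group,
                                   behavioural = bp)
  }

  report <- structure(list(
    provenance = list(package = "oscpls",
                      version = as.character(utils::packageVersion("oscpls")),
                      seed = seed, config_hash = config_hash(unclass(config)),
                      n_perm = plan$n_perm, n_boot = plan$n_boot,
                      alpha = plan$alpha, centering = plan$centering,
                      permutation_scheme = plan$scheme),
    behaviour = list(table = behaviour, group_stats = stats_tbl,
                     outliers = outliers[, c("subject", "group",
                                             "accuracy_outlier",
                                             "rt_outlier")],
                     response_locked_counts = rl_counts),
    contrasts = contrast_results), class = "run_report")
  log_line("done in %.1f s", proc.time()[["elapsed"]] - t_start)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed ", x$provenance$seed, ", config ",
      x$provenance$config_hash, ")\n", sep = "")
  for (nm in names(x$contrasts)) {
    cr <- x$contrasts[[nm]]
    cat(sprintf("  %s: task LV1 sigma = %.3g (%.1f%%, p = %.3g); behavioural LV1 p = %.3g\n",
                nm, cr$task$singular_values[1], cr$task$crossblock_pct[1],
                cr$task$perm_p[1], cr$behavioural$perm_p[1]))
  }
  invisible(x)
}

#' Numeric summary of a run report
#'
#' Flattens a [run_pipeline()] report into the machine-readable structure
#' written by [export_report()]: per contrast the singular values,
#' crossblock percentages, permutation p-values, reliable-element counts
#' and per-group behaviour correlations with CIs, plus the behavioural
#' statistics and provenance.
#'
#' @param report a `run_report`.
#' @return nested list of scalars, vectors and small tables.
#' @export
report_summary <- function(report) {
  stopifnot(inherits(report, "run_report"))
  summ_task <- function(t) list(
    singular_values = t$singular_values,
    crossblock_pct = t$crossblock_pct,
    perm_p = t$perm_p,
    n_reliable = as.integer(colSums(t$reliable_mask)))
  contrasts <- lapply(report$contrasts, function(cr) {
    out <- list(task = summ_task(cr$task))
    if (length(cr$task_by_group))
      out$task_by_group <- lapply(cr$task_by_group, summ_task)
    bp <- cr$behavioural
    out$behavioural <- list(
      singular_values = bp$singular_values,
      crossblock_pct = bp$crossblock_pct,
      perm_p = bp$perm_p,
      n_reliable = as.integer(colSums(bp$reliable_mask)),
      behav_corr_lv1 = as.list(bp$behav_corr[, 1]),
      behav_corr_lv1_ci_lo = as.list(bp$behav_corr_ci_lo[, 1]),
      behav_corr_lv1_ci_hi = as.list(bp$behav_corr_ci_hi[, 1]))
    out
  })
  gs <- report$behaviour$group_stats
  list(provenance = report$provenance,
       behaviour = list(
         group_stats = split(gs[, setdiff(names(gs), "measure")],
                             gs$measure),
         n_rt_outliers = sum(report$behaviour$outliers$rt_outlier),
         response_locked_counts = stats::setNames(
           as.list(report$behaviour$response_locked_counts$n_retained),
           report$behaviour$response_locked_counts$subject)),
       contrasts = contrasts)
}

#' Export a run report
#'
#' Writes `report.json` (the [report_summary()], full precision), one
#' salience table per contrast
#' (`salience_<contrast>.tsv`: channel, band, brain salience, bootstrap SE,
#' ratio, CI and reliability for LV1), the behaviour table, and a plain-text
#' `summary.txt` listing the reliable channels per band with the sign of
#' their salience.
#'
#' @param report a `run_report`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
export_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  summ <- report_summary(report)
  # I(17) significant digits: doubles survive the write/read round trip bit
  # for bit
  jsonlite::write_json(summ, file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  write_behaviour_table(report$behaviour$table,
                        file.path(path, "behaviour.tsv"))
  lines <- c("oscpls run summary",
             paste0("seed ", report$provenance$seed, ", config ",
                    report$provenance$config_hash), "")
  for (nm in names(report$contrasts)) {
    cr <- report$contrasts[[nm]]
    t <- cr$task
    tab <- data.frame(channel = t$cols$channel, band = t$cols$band,
                      salience = t$brain_saliences[, 1],
                      boot_se = t$boot_se[, 1],
                      boot_ratio = t$boot_ratio[, 1],
                      ci_lo = t$boot_ci_lo[, 1], ci_hi = t$boot_ci_hi[, 1],
                      reliable = t$reliable_mask[, 1])
    utils::write.table(tab, file.path(path, paste0("salience_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    lines <- c(lines, sprintf(
      "%s (task - baseline = %s - %s): LV1 sigma = %.4g, %.1f%% crossblock, p = %.4g",
      nm, cr$definition$task, cr$definition$baseline,
      t$singular_values[1], t$crossblock_pct[1], t$perm_p[1]))
    rel <- tab[tab$reliable, ]
    if (nrow(rel)) {
      for (b in unique(rel$band)) {
        rb <- rel[rel$band == b, ]
        lines <- c(lines, sprintf("  %s: %s", b,
                                  paste0(rb$channel,
                                         ifelse(rb$salience > 0, "(+)", "(-)"),
                                         collapse = " ")))
      }
    } else lines <- c(lines, "  no reliable elements")
    bc <- cr$behavioural$behav_corr[, 1]
    lines <- c(lines, sprintf("  behavioural LV1 p = %.4g; correlations: %s",
                              cr$behavioural$perm_p[1],
                              paste(sprintf("%s = %.2f", names(bc), bc),
                                    collapse = ", ")), "")
  }
  writeLines(lines, file.path(path, "summary.txt"))
  invisible(path)
}

#' @rdname export_report
#' @param path directory a report was exported to.
#' @return `import_report` returns the parsed `report.json`.
#' @export
import_report <- function(path) {
  jsonlite::read_json(file.path(path, "report.json"), simplifyVector = TRUE)
}

#' Quick self-check of the PLS core
#'
#' Runs a set of fast internal oracle checks (hand-computable task PLS
#' case, crossblock percentages, behavioural-PLS closed form) and errors on
#' the first failure.  Used by the command-line `selftest` verb.
#'
#' @return `TRUE` invisibly.
#' @export
pls_selftest <- function() {
  # 1 group x 2 conditions, cell means [[1,0],[0,1]]
  X <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  tm <- list(X = X, rows = data.frame(
    subject = c("s1", "s2", "s1", "s2"), group = "g",
    condition = rep(c("a", "b"), each = 2), stringsAsFactors = FALSE),
    cols = data.frame(channel = c("c1", "c2"), band = "theta"),
    conditions = c("a", "b"), groups = "g")
  class(tm) <- "task_matrix"
  fit <- mean_centered_pls(tm)
  stopifnot(abs(fit$singular_values[1] - 1) < 1e-12,
            max(abs(abs(fit$brain_saliences[, 1]) - 1 / sqrt(2))) < 1e-12,
            max(abs(abs(fit$design_saliences[, 1]) - 1 / sqrt(2))) < 1e-12)
  stopifnot(max(abs(crossblock_pct(c(3, 4)) - c(36, 64))) < 1e-12)
  # behavioural closed form: sigma = ||r||, salience = r / ||r||
  set.seed(7)
  n <- 40; p <- 5
  brain <- matrix(stats::rnorm(n * p), n, p,
                  dimnames = list(sprintf("s%02d", 1:n), NULL))
  behav <- data.frame(subject = rownames(brain),
                      m = stats::rnorm(n))
  r <- drop(stats::cor(behav$m, brain))
  bp <- behavioural_pls(brain, behav, "m",
                        group = rep("g", n), n_perm = 10, n_boot = 10,
                        seed = 1)
  stopifnot(abs(bp$singular_values[1] - sqrt(sum(r^2))) < 1e-10,
            max(abs(bp$brain_saliences[, 1] * sign(r[which.max(abs(r))]) -
                      r / sqrt(sum(r^2)))) < 1e-10)
  invisible(TRUE)
}
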