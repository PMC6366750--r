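#!/usr/bin/env Rscript
# Thin command-line wrapper over the oscpls pipeline functions.
#
#   Rscript scripts/run_pipeline.R <verb> [flags]
#
# Verbs:
#   simulate  write the simulated power tensor, trials and ground truth
#   analyze   run the full pipeline and export the report
#   report    print the human-readable summary of an exported report
#   selftest  run the built-in PLS core oracle checks
#
# Flags: --config PATH (YAML/JSON sim config), --seed INT, --out DIR,
#        --n-perm INT, --n-boot INT, --theta-variant {2-7,4-7},
#        --baseline {first-study,pre-stimulus}

suppressMessages(library(oscpls))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L)
  stop("usage: run_pipeline.R {simulate|analyze|report|selftest} [flags]")
verb <- args[1]
flag <- function(name, default = NULL) {
  i <- which(args == name)
  if (length(i) == 1L && i < length(args)) args[i + 1L] else default
}

seed <- as.integer(flag("--seed", "1"))
out <- flag("--out", "oscpls_out")
theta <- flag("--theta-variant", "2-7")
baseline <- flag("--baseline", "first-study")

load_config <- function() {
  path <- flag("--config")
  if (is.null(path)) sim_config(bands = band_set(theta))
  else read_sim_config(path)
}

if (verb == "selftest") {
  pls_selftest()
  cat("selftest passed\n")
} else if (verb == "simulate") {
  cfg <- load_config()
  ds <- simulate_power_dataset(cfg, seed = seed)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_power_long(ds$power, file.path(out, "power_long.tsv"))
  utils::write.table(ds$trials, file.path(out, "trials.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_behaviour_table(behaviour_table(ds$trials, ds$subjects),
                        file.path(out, "behaviour.tsv"))
  write_ground_truth(ds$ground_truth, file.path(out, "ground_truth.json"))
  cat("simulated dataset written to", out, "\n")
} else if (verb == "analyze") {
  cfg <- load_config()
  plan <- analysis_plan(
    test_baseline = if (baseline == "pre-stimulus") "pre_stimulus" else
      "first_study",
    response_baseline = if (baseline == "pre-stimulus") "pre_stimulus" else
      "first_study_short",
    n_perm = as.integer(flag("--n-perm", "1000")),
    n_boot = as.integer(flag("--n-boot", "1000")))
  report <- run_pipeline(cfg, plan, seed = seed)
  export_report(report, out)
  cat("report written to", out, "\n")
} else if (verb == "report") {
  cat(readLines(file.path(out, "summary.txt")), sep = "\n")
} else {
  stop("unknown verb '", verb, "'")
}
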