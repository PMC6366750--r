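#' Read a simulation configuration from YAML or JSON
#'
#' Accepts every [sim_config()] field; scalar fields map directly, `bands`
#' is a list of `{name, f_lo, f_hi}` records, `effects` a list of
#' [effect_spec()] records and `coupling` a [coupling_spec()] record.
#' Unknown keys are rejected.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return a validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be a .yaml/.yml or .json file")
  if (!is.list(raw)) stop("config file must contain a mapping")

  allowed <- c("n_per_group", "groups", "n_channels", "bands",
               "window_variant", "conditions", "n_trials", "effects",
               "coupling", "behaviour_model", "noise_sd", "subject_sd",
               "baseline_log_power", "log_power", "sdlog_trial", "p_fast",
               "fast_range_ms", "practice_ms", "channels", "timecourse",
               "seed")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))

  args <- raw
  if (!is.null(raw$bands))
    args$bands <- lapply(seq_len(record_count(raw$bands)), function(i) {
      b <- record_at(raw$bands, i)
      band_definition(b$name, b$f_lo, b$f_hi)
    })
  if (!is.null(raw$effects))
    args$effects <- lapply(seq_len(record_count(raw$effects)), function(i) {
      e <- record_at(raw$effects, i)
      effect_spec(unlist(e$channels), unlist(e$bands), unlist(e$conditions),
                  e$magnitude, group = e$group)
    })
  if (!is.null(raw$coupling)) {
    cp <- raw$coupling
    args$coupling <- coupling_spec(
      group = cp$group, channels = unlist(cp$channels),
      bands = unlist(cp$bands), condition = cp$condition,
      baseline = cp$baseline %||% "first_study", r = cp$r,
      strength = cp$strength %||% 1)
  }
  if (!is.null(raw$baseline_log_power))
    args$baseline_log_power <- unlist(raw$baseline_log_power)
  if (!is.null(raw$fast_range_ms)) args$fast_range_ms <- unlist(raw$fast_range_ms)
  if (!is.null(raw$groups)) args$groups <- unlist(raw$groups)
  if (!is.null(raw$conditions)) args$conditions <- unlist(raw$conditions)
  if (!is.null(raw$channels)) args$channels <- unlist(raw$channels)
  do.call(sim_config, args)
}

# jsonlite may simplify a list of records to a data.frame; yaml keeps lists.
record_count <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
record_at <- function(x, i) {
  if (is.data.frame(x)) as.list(x[i, , drop = FALSE]) else x[[i]]
}
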