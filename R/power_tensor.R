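#' Construct a power tensor
#'
#' The power tensor holds per-subject, per-condition (task window),
#' per-channel, per-band oscillatory power — the input block for the PLS
#' stage.  Values are natural-log mean power by default.
#'
#' @param values numeric array `subject x condition x channel x band` with no
#'   missing entries.
#' @param subject,condition,channel,band axis labels (character).
#' @param group character vector, one group label per subject.
#' @param log_power logical flag recording the power scale.
#' @return an object of class `power_tensor`.
#' @export
power_tensor <- function(values, subject, condition, channel, band, group,
                         log_power = TRUE) {
  stopifnot(is.array(values), length(dim(values)) == 4L)
  d <- dim(values)
  stopifnot(length(subject) == d[1], length(condition) == d[2],
            length(channel) == d[3], length(band) == d[4],
            length(group) == d[1])
  if (anyNA(values)) stop("power tensor contains missing entries")
  if (anyDuplicated(subject)) stop("duplicate subject labels")
  dimnames(values) <- list(subject = as.character(subject),
                           condition = as.character(condition),
                           channel = as.character(channel),
                           band = as.character(band))
  structure(list(values = values,
                 group = stats::setNames(as.character(group),
                                         as.character(subject)),
                 log_power = isTRUE(log_power)),
            class = "power_tensor")
}

#' @export
print.power_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "power_tensor: %d subjects (%s), %d conditions, %d channels, %d bands [%s power]\n",
    d[1], paste(sprintf("%s n=%d", names(table(x$group)), table(x$group)),
                collapse = ", "),
    d[2], d[3], d[4], if (x$log_power) "log" else "linear"))
  cat("conditions:", paste(dimnames(x$values)$condition, collapse = ", "), "\n")
  invisible(x)
}

#' Long-format conversion of a power tensor
#'
#' @param x a [power_tensor()].
#' @param ... unused.
#' @return data.frame with columns subject, group, condition, channel, band,
#'   power — the on-disk interchange format.
#' @export
as.data.frame.power_tensor <- function(x, ...) {
  dn <- dimnames(x$values)
  long <- expand.grid(subject = dn$subject, condition = dn$condition,
                      channel = dn$channel, band = dn$band,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$group <- unname(x$group[long$subject])
  long$power <- as.vector(x$values)
  long[, c("subject", "group", "condition", "channel", "band", "power")]
}

#' Read and write power tensors as delimited text
#'
#' Long format, tab-separated, columns subject, group, condition, channel,
#' band, power.  `read_power_long` restores the tensor with axes ordered as
#' they first appear in the file, so a write/read round trip reproduces the
#' tensor exactly.
#'
#' @param x a [power_tensor()].
#' @param path file path.
#' @param log_power power-scale flag recorded on the restored tensor.
#' @return `write_power_long` returns `path` invisibly; `read_power_long`
#'   returns a [power_tensor()].
#' @export
write_power_long <- function(x, path) {
  stopifnot(inherits(x, "power_tensor"))
  df <- as.data.frame(x)
  # 17 significant digits so the write/read round trip is exact
  df$power <- sprintf("%.17g", df$power)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_power_long
#' @export
read_power_long <- function(path, log_power = TRUE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(subject = "character",
                                         group = "character",
                                         condition = "character",
                                         channel = "character",
                                         band = "character",
                                         power = "numeric"))
  need <- c("subject", "group", "condition", "channel", "band", "power")
  if (!all(need %in% names(df)))
    stop("power file must have columns: ", paste(need, collapse = ", "))
  subj <- unique(df$subject); cond <- unique(df$condition)
  chan <- unique(df$channel); band <- unique(df$band)
  vals <- array(NA_real_, c(length(subj), length(cond), length(chan),
                            length(band)))
  idx <- cbind(match(df$subject, subj), match(df$condition, cond),
               match(df$channel, chan), match(df$band, band))
  if (anyDuplicated(idx)) stop("duplicate (subject, condition, channel, band) rows")
  vals[idx] <- df$power
  if (anyNA(vals)) stop("incomplete power file: missing cells")
  grp <- df$group[match(subj, df$subject)]
  power_tensor(vals, subj, cond, chan, band, grp, log_power = log_power)
}

#' Per-subject window contrast from a power tensor
#'
#' Extracts the `subject x channel x band` slices of two conditions and
#' returns their difference (`task - baseline`) as the one-contrast-per-
#' subject brain block used by the behavioural PLS.
#'
#' @param x a [power_tensor()].
#' @param task,baseline condition labels; the contrast is `task - baseline`.
#' @return array `subject x channel x band` of power differences, with the
#'   subject-to-group map attached as attribute `"group"`.
#' @export
condition_contrast <- function(x, task, baseline) {
  stopifnot(inherits(x, "power_tensor"))
  cond <- dimnames(x$values)$condition
  for (cc in c(task, baseline))
    if (!cc %in% cond) stop("condition '", cc, "' not in tensor")
  out <- window_contrast(x$values[, task, , , drop = TRUE],
                         x$values[, baseline, , , drop = TRUE])
  attr(out, "group") <- x$group
  out
}

#' Contrast matrix for the behavioural PLS
#'
#' Flattens the per-subject window contrast (`task - baseline`) into the
#' one-row-per-subject brain block the behavioural PLS consumes, with
#' columns in task-matrix order (channel-major, band within channel) and
#' the subject-to-group map attached.
#'
#' @inheritParams condition_contrast
#' @return numeric matrix `subject x (channel x band)` with attributes
#'   `"channel"`, `"band"` and `"group"`.
#' @export
contrast_matrix <- function(x, task, baseline) {
  flatten_contrast(condition_contrast(x, task, baseline))
}

# Flatten a subject x channel x band array into subject x (channel-major,
# band-within-channel) columns, matching the task-matrix column order.
flatten_contrast <- function(contrast) {
  d <- dim(contrast); dn <- dimnames(contrast)
  stopifnot(length(d) == 3L)
  m <- matrix(NA_real_, d[1], d[2] * d[3])
  cols <- character(d[2] * d[3])
  k <- 0L
  for (ch in seq_len(d[2])) for (b in seq_len(d[3])) {
    k <- k + 1L
    m[, k] <- contrast[, ch, b]
    cols[k] <- paste(dn[[2]][ch], dn[[3]][b], sep = ".")
  }
  dimnames(m) <- list(dn[[1]], cols)
  attr(m, "channel") <- rep(dn[[2]], each = d[3])
  attr(m, "band") <- rep(dn[[3]], times = d[2])
  attr(m, "group") <- attr(contrast, "group")
  m
}
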