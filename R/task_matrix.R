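#' Build the task data matrix for mean-centered PLS
#'
#' Stacks band power into the 2-D layout the task PLS decomposes: one row
#' per participant within condition within group, one column per channel x
#' band.  Row order is deterministic — group-major, condition within group,
#' subject within condition (subjects in tensor order) — and column order is
#' channel-major with band varying within channel, so identical data always
#' yield an identical matrix regardless of input record order.
#'
#' @param power a [power_tensor()].
#' @param conditions ordered condition labels to include (default: all, in
#'   tensor order).
#' @param groups ordered group labels to include (default: all, in order of
#'   first appearance).
#' @return an object of class `task_matrix`: list with `X` (numeric matrix),
#'   `rows` (data.frame subject/group/condition), `cols` (data.frame
#'   channel/band), `conditions`, `groups`.
#' @export
build_task_matrix <- function(power, conditions = NULL, groups = NULL) {
  stopifnot(inherits(power, "power_tensor"))
  dn <- dimnames(power$values)
  conditions <- conditions %||% dn$condition
  groups <- groups %||% unique(unname(power$group))
  if (!all(conditions %in% dn$condition))
    stop("condition(s) not in tensor: ",
         paste(setdiff(conditions, dn$condition), collapse = ", "))
  if (!all(groups %in% power$group))
    stop("group(s) not in tensor: ",
         paste(setdiff(groups, unique(power$group)), collapse = ", "))

  nCh <- length(dn$channel); nB <- length(dn$band)
  cols <- data.frame(channel = rep(dn$channel, each = nB),
                     band = rep(dn$band, times = nCh),
                     stringsAsFactors = FALSE)

  rows <- NULL
  blocks <- list()
  k <- 0L
  for (g in groups) {
    subj_g <- dn$subject[power$group[dn$subject] == g]
    for (cc in conditions) {
      sl <- power$values[subj_g, cc, , , drop = FALSE]
      # subject x (channel-major, band-within-channel) block
      m <- matrix(NA_real_, length(subj_g), nCh * nB)
      jj <- 0L
      for (ch in seq_len(nCh)) for (b in seq_len(nB)) {
        jj <- jj + 1L
        m[, jj] <- sl[, 1L, ch, b]
      }
      k <- k + 1L
      blocks[[k]] <- m
      rows <- rbind(rows, data.frame(subject = subj_g, group = g,
                                     condition = cc, stringsAsFactors = FALSE))
    }
  }
  X <- do.call(rbind, blocks)
  colnames(X) <- paste(cols$channel, cols$band, sep = ".")
  rownames(X) <- paste(rows$subject, rows$condition, sep = ":")
  structure(list(X = X, rows = rows, cols = cols,
                 conditions = conditions, groups = groups),
            class = "task_matrix")
}

#' @export
print.task_matrix <- function(x, ...) {
  cat(sprintf("task_matrix: %d rows (%d group(s) x %d condition(s)), %d columns (channel x band)\n",
              nrow(x$X), length(x$groups), length(x$conditions), ncol(x$X)))
  invisible(x)
}

# Cell index (1..n_cells) of each row; cells ordered group-major, condition
# within group — the canonical ordering every PLS routine relies on.
cell_index <- function(tm) {
  cells <- expand.grid(condition = tm$conditions, group = tm$groups,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- cells[, c("group", "condition")]
  idx <- match(paste(tm$rows$group, tm$rows$condition),
               paste(cells$group, cells$condition))
  list(cells = cells, idx = idx)
}
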