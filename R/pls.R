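#' Mean-centered task PLS decomposition
#'
#' Computes the group x condition cell means of the task data matrix,
#' centers them, and decomposes the centered cell-mean matrix with SVD.
#' Each latent variable (LV) comprises a design salience (contrast over
#' cells), a brain salience (weights over channel x band columns) and a
#' singular value; brain scores are the projections of the (identically
#' centered) participant rows onto the brain saliences.
#'
#' Centering variants: `"grand"` (default) removes the grand mean of the
#' cell means from every column, so LVs may express both group and condition
#' effects; `"within_condition"` removes each condition's mean across
#' groups, restricting LVs to group differences within condition.
#'
#' The sign of each LV is fixed by making the largest-magnitude brain
#' salience element positive, so output is deterministic across platforms.
#'
#' @param tm a [build_task_matrix()] result.
#' @param centering `"grand"` or `"within_condition"`.
#' @return an object of class `mcpls`: singular values (descending), design
#'   and brain saliences, brain scores, crossblock covariance percentages,
#'   the cell table, and a `degenerate` flag (all singular values zero).
#' @export
mean_centered_pls <- function(tm, centering = c("grand", "within_condition")) {
  centering <- match.arg(centering)
  stopifnot(inherits(tm, "task_matrix"))
  ci <- cell_index(tm)
  if (nrow(ci$cells) < 2L) stop("need at least 2 group x condition cells")
  M <- cell_means(tm$X, ci$idx, nrow(ci$cells))
  cen <- center_cells(M, ci$cells, centering)
  fit <- svd_saliences(cen$Mc)

  # participant rows centered by the same column offsets as their cell
  Xc <- tm$X - cen$offsets[ci$idx, , drop = FALSE]
  scores <- Xc %*% fit$V
  rownames(scores) <- rownames(tm$X)

  structure(list(
    singular_values = fit$d,
    design_saliences = fit$U,
    brain_saliences = fit$V,
    brain_scores = scores,
    crossblock_pct = if (fit$degenerate) rep(NA_real_, length(fit$d)) else
      crossblock_pct(fit$d),
    cells = ci$cells, cell_mean_matrix = M, centered_cell_means = cen$Mc,
    centering = centering, degenerate = fit$degenerate,
    rows = tm$rows, cols = tm$cols), class = "mcpls")
}

cell_means <- function(X, idx, n_cells) {
  cnt <- tabulate(idx, n_cells)
  if (any(cnt == 0L)) stop("empty group x condition cell")
  rowsum(X, idx, reorder = TRUE) / cnt
}

center_cells <- function(M, cells, centering) {
  if (centering == "grand") {
    gm <- colMeans(M)
    offsets <- matrix(gm, nrow(M), ncol(M), byrow = TRUE)
  } else {
    offsets <- matrix(NA_real_, nrow(M), ncol(M))
    for (cc in unique(cells$condition)) {
      rows <- which(cells$condition == cc)
      offsets[rows, ] <- matrix(colMeans(M[rows, , drop = FALSE]),
                                length(rows), ncol(M), byrow = TRUE)
    }
  }
  list(Mc = M - offsets, offsets = offsets)
}

# SVD with descending singular values and the deterministic sign convention
# (largest-|.| brain-salience element positive per LV).
svd_saliences <- function(Mc) {
  s <- svd(Mc)
  degenerate <- max(s$d) < 1e-12
  U <- s$u; V <- s$v
  for (i in seq_along(s$d)) {
    j <- which.max(abs(V[, i]))
    if (V[j, i] < 0) { V[, i] <- -V[, i]; U[, i] <- -U[, i] }
  }
  list(d = s$d, U = U, V = V, degenerate = degenerate)
}

#' @export
print.mcpls <- function(x, ...) {
  cat("mean-centered task PLS (", x$centering, " centering)\n", sep = "")
  if (x$degenerate) cat("  degenerate: all singular values zero\n")
  for (i in seq_along(x$singular_values))
    cat(sprintf("  LV%d: sigma = %.4g, crossblock = %.1f%%\n", i,
                x$singular_values[i], x$crossblock_pct[i]))
  invisible(x)
}

#' Crossblock covariance percentages
#'
#' Share of the cross-block covariance captured by each LV,
#' `100 * sigma_i^2 / sum(sigma_j^2)`; always sums to 100.
#'
#' @param sigma non-negative singular values, not all zero.
#' @return numeric vector of percentages.
#' @examples
#' crossblock_pct(c(3, 4))  # 36, 64
#' @export
crossblock_pct <- function(sigma) {
  stopifnot(is.numeric(sigma), all(is.finite(sigma)), all(sigma >= 0))
  tot <- sum(sigma^2)
  if (tot == 0) stop("all singular values are zero")
  100 * sigma^2 / tot
}

#' Permutation test on singular values
#'
#' Randomly reassigns participants' data to the group x condition cells,
#' recomputes the mean-centered PLS for each reordering, and reports, per
#' LV, the fraction of permuted singular values at least as large as the
#' observed one: `p_i = #\{sigma_i^perm >= sigma_i^obs\} / n_perm`.
#'
#' Schemes differ in what is reassigned, and all of them keep each
#' subject's rows together so that within-subject correlation (a subject
#' intercept common to all of a subject's conditions) does not distort the
#' permutation distribution:
#' \describe{
#'   \item{`"subjects"` (default)}{condition labels are permuted within
#'     subject and subjects are reassigned to groups; the null covers both
#'     condition and group effects.}
#'   \item{`"conditions_only"`}{condition labels permuted within subject,
#'     group assignment fixed.}
#'   \item{`"rows"`}{every row relabelled freely across all cells.  This
#'     literal variant ignores the subject blocking and is exact only when
#'     rows are independent (no subject intercept); retained for
#'     comparison.}
#' }
#'
#' @param tm a [build_task_matrix()] result.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @param scheme `"subjects"`, `"conditions_only"` or `"rows"`.
#' @param centering passed to [mean_centered_pls()].
#' @param add_one add-one smoothing `(k + 1) / (n_perm + 1)`; off by
#'   default, which follows the literal counting rule.
#' @return list with `perm_p` (per LV), `n_perm`, `scheme`, `seed`.
#' @export
pls_permutation <- function(tm, n_perm = 1000, seed = NULL,
                            scheme = c("subjects", "conditions_only",
                                       "rows"),
                            centering = "grand", add_one = FALSE) {
  scheme <- match.arg(scheme)
  if (!is_count(n_perm, 1L)) stop("n_perm must be a count >= 1")
  ci <- cell_index(tm)
  n_cells <- nrow(ci$cells)
  M <- cell_means(tm$X, ci$idx, n_cells)
  obs <- svd(center_cells(M, ci$cells, centering)$Mc, nu = 0, nv = 0)$d

  rs <- if (scheme != "rows") subject_rows(tm)
  if (!is.null(rs)) {
    subj <- rownames(rs$row_of)
    group_of <- tm$rows$group[match(subj, tm$rows$subject)]
    n_cond <- length(tm$conditions)
    # cell id for (group index, condition index)
    cell_of <- matrix(match(
      paste(rep(tm$groups, each = n_cond), rep(tm$conditions, length(tm$groups))),
      paste(ci$cells$group, ci$cells$condition)),
      nrow = length(tm$groups), byrow = TRUE)
  }

  count <- numeric(length(obs))
  withr::with_seed(if (is.null(seed)) NULL else derive_seed(seed, "perm"), {
    for (b in seq_len(n_perm)) {
      if (scheme == "rows") {
        idx_p <- ci$idx[sample.int(length(ci$idx))]
      } else {
        g_assign <- match(group_of, tm$groups)
        if (scheme == "subjects")
          g_assign <- g_assign[sample.int(length(g_assign))]
        idx_p <- integer(nrow(tm$X))
        for (s in seq_along(subj)) {
          cond_p <- sample.int(n_cond)
          idx_p[rs$row_of[s, ]] <- cell_of[g_assign[s], cond_p]
        }
      }
      Mp <- cell_means(tm$X, idx_p, n_cells)
      dp <- svd(center_cells(Mp, ci$cells, centering)$Mc, nu = 0, nv = 0)$d
      count <- count + (dp >= obs - 1e-12)
    }
  })
  p <- if (add_one) (count + 1) / (n_perm + 1) else count / n_perm
  list(perm_p = p, n_perm = as.integer(n_perm), scheme = scheme,
       centering = centering, seed = seed)
}

#' Bootstrap estimation of salience reliability
#'
#' Resamples subjects with replacement within group, keeping each subject's
#' condition rows together and the condition assignment fixed, recomputes
#' the mean-centered PLS for every draw, aligns each bootstrap salience set
#' to the original by orthogonal Procrustes rotation (absorbing the sign and
#' order indeterminacy of the SVD), and summarises, per brain-salience
#' element: bootstrap SE, bootstrap ratio (salience / SE), and the
#' percentile `1 - alpha` confidence interval.  An element is marked
#' reliable when its CI excludes zero.
#'
#' Draws in which a group contains fewer than two distinct subjects are
#' rejected and redrawn (up to `retry_cap` retries in total).
#'
#' @param tm a [build_task_matrix()] result.
#' @param fit the [mean_centered_pls()] fit to align against (computed if
#'   omitted).
#' @param n_boot number of bootstrap draws (>= 2).
#' @param seed integer seed.
#' @param alpha CI level complement (default 0.05 for 95% bounds).
#' @param retry_cap maximum degenerate draws tolerated.
#' @param keep_draws keep the aligned salience draws (needed by callers that
#'   derive further bootstrap distributions).
#' @return list with `boot_se`, `boot_ratio`, `boot_ci_lo`, `boot_ci_hi`,
#'   `reliable_mask` (all p x k like the brain saliences), the design-side
#'   analogues (`design_se` etc.), `n_boot`, `alpha`, `n_retries`, and a
#'   `degenerate_se` flag when any SE is exactly zero.
#' @export
pls_bootstrap <- function(tm, fit = NULL, n_boot = 1000, seed = NULL,
                          alpha = 0.05, retry_cap = 100, keep_draws = FALSE) {
  if (!is_count(n_boot, 2L)) stop("n_boot must be a count >= 2")
  fit <- fit %||% mean_centered_pls(tm)
  ci <- cell_index(tm)
  rs <- subject_rows(tm)
  for (g in names(rs$subjects_by_group))
    if (length(rs$subjects_by_group[[g]]) < 2L)
      stop("need >= 2 subjects per group for the bootstrap")

  k <- length(fit$singular_values)
  p <- nrow(fit$brain_saliences)
  Vdraws <- array(NA_real_, c(p, k, n_boot))
  Udraws <- array(NA_real_, c(nrow(fit$design_saliences), k, n_boot))
  n_retries <- 0L
  withr::with_seed(if (is.null(seed)) NULL else derive_seed(seed, "boot"), {
    b <- 1L
    while (b <= n_boot) {
      draw <- draw_cell_means(tm, ci, rs)
      if (is.null(draw)) {
        n_retries <- n_retries + 1L
        if (n_retries > retry_cap)
          stop("bootstrap retry cap exceeded: too few distinct subjects")
        next
      }
      sb <- svd_saliences(center_cells(draw, ci$cells, fit$centering)$Mc)
      Q <- procrustes_rotation(sb$V[, seq_len(k), drop = FALSE],
                               fit$brain_saliences)
      Vdraws[, , b] <- sb$V[, seq_len(k), drop = FALSE] %*% Q
      Udraws[, , b] <- sb$U[, seq_len(k), drop = FALSE] %*% Q
      b <- b + 1L
    }
  })
  out <- summarise_draws(Vdraws, fit$brain_saliences, alpha)
  des <- summarise_draws(Udraws, fit$design_saliences, alpha)
  res <- list(boot_se = out$se, boot_ratio = out$ratio,
              boot_ci_lo = out$lo, boot_ci_hi = out$hi,
              reliable_mask = out$reliable,
              design_se = des$se, design_ci_lo = des$lo,
              design_ci_hi = des$hi,
              n_boot = as.integer(n_boot), alpha = alpha,
              n_retries = n_retries,
              degenerate_se = any(out$se == 0), seed = seed)
  if (keep_draws) res$draws <- Vdraws
  res
}

# Map each (subject, condition) to its row; subjects listed per group.
subject_rows <- function(tm) {
  subj <- unique(tm$rows$subject)
  row_of <- matrix(NA_integer_, length(subj), length(tm$conditions),
                   dimnames = list(subj, tm$conditions))
  for (r in seq_len(nrow(tm$rows)))
    row_of[tm$rows$subject[r], tm$rows$condition[r]] <- r
  if (anyNA(row_of)) stop("every subject must appear once per condition")
  grp <- tm$rows$group[match(subj, tm$rows$subject)]
  list(row_of = row_of,
       subjects_by_group = split(subj, factor(grp, levels = tm$groups)))
}

# One bootstrap draw of the cell-mean matrix, or NULL when a group draw has
# fewer than two distinct subjects.
draw_cell_means <- function(tm, ci, rs) {
  M <- matrix(NA_real_, nrow(ci$cells), ncol(tm$X))
  for (g in tm$groups) {
    sg <- rs$subjects_by_group[[g]]
    take <- sg[sample.int(length(sg), replace = TRUE)]
    if (length(unique(take)) < 2L) return(NULL)
    for (cc in tm$conditions) {
      cell <- which(ci$cells$group == g & ci$cells$condition == cc)
      M[cell, ] <- colMeans(tm$X[rs$row_of[take, cc], , drop = FALSE])
    }
  }
  M
}

# Orthogonal alignment of a bootstrap salience set onto the original,
# restricted to signed permutations: bootstrap LVs are matched to original
# LVs greedily by |correlation| and sign-flipped to agree.  This handles
# the SVD's sign and order indeterminacy.  An unrestricted Procrustes
# rotation is deliberately not used for the per-element summaries: when the
# retained set includes weak (near-degenerate) LVs, the free rotation pulls
# every bootstrap draw toward the projection of the original saliences onto
# the bootstrap subspace, shrinking the apparent bootstrap dispersion and
# invalidating the percentile intervals.
procrustes_rotation <- function(Vb, V0) {
  C <- crossprod(Vb, V0)
  k <- ncol(C)
  Q <- matrix(0, k, k)
  rows <- seq_len(k); cols <- seq_len(k)
  for (step in seq_len(k)) {
    sub <- abs(C[rows, cols, drop = FALSE])
    pos <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    j <- rows[pos[1]]; i <- cols[pos[2]]
    Q[j, i] <- if (C[j, i] < 0) -1 else 1
    rows <- rows[rows != j]; cols <- cols[cols != i]
  }
  Q
}

# Percentile summaries over the third (draw) dimension.  Quantile type 1
# (inverse empirical CDF) so that with two draws the CI is their min/max.
summarise_draws <- function(draws, center, alpha) {
  se <- apply(draws, c(1, 2), stats::sd)
  lo <- apply(draws, c(1, 2), stats::quantile, probs = alpha / 2, type = 1)
  hi <- apply(draws, c(1, 2), stats::quantile, probs = 1 - alpha / 2, type = 1)
  ratio <- center / se
  ratio[se == 0] <- NA_real_
  list(se = se, ratio = ratio, lo = lo, hi = hi,
       reliable = lo > 0 | hi < 0)
}

#' Task PLS with full inference
#'
#' Convenience wrapper running [mean_centered_pls()], [pls_permutation()]
#' and [pls_bootstrap()] and collecting the results with their settings.
#'
#' @inheritParams pls_permutation
#' @inheritParams pls_bootstrap
#' @param n_perm,n_boot resampling sizes.
#' @return object of class `pls_result` extending the `mcpls` fit with
#'   `perm_p` and the bootstrap fields, plus a `settings` list (seed,
#'   n_perm, n_boot, centering, permutation scheme).
#' @export
task_pls <- function(tm, n_perm = 1000, n_boot = 1000, seed = NULL,
                     centering = "grand", scheme = "subjects", alpha = 0.05) {
  fit <- mean_centered_pls(tm, centering)
  perm <- pls_permutation(tm, n_perm = n_perm, seed = seed, scheme = scheme,
                          centering = centering)
  boot <- pls_bootstrap(tm, fit = fit, n_boot = n_boot, seed = seed,
                        alpha = alpha)
  fit$perm_p <- perm$perm_p
  fit[names(boot)] <- boot
  fit$settings <- list(seed = seed, n_perm = perm$n_perm,
                       n_boot = boot$n_boot, centering = centering,
                       scheme = scheme, alpha = alpha)
  class(fit) <- c("pls_result", "mcpls")
  fit
}

#' @export
print.pls_result <- function(x, ...) {
  cat("task PLS (", x$centering, " centering, scheme ", x$settings$scheme,
      ", ", x$settings$n_perm, " perms, ", x$settings$n_boot, " boots)\n",
      sep = "")
  for (i in seq_along(x$singular_values))
    cat(sprintf("  LV%d: sigma = %.4g, crossblock = %.1f%%, p = %.4g, %d reliable element(s)\n",
                i, x$singular_values[i], x$crossblock_pct[i], x$perm_p[i],
                sum(x$reliable_mask[, i])))
  invisible(x)
}

#' Behavioural PLS
#'
#' Decomposes the stacked within-group cross-correlation matrix between
#' behavioural measures and brain columns.  For each group, every measure is
#' Pearson-correlated with every brain column (one contrast row per
#' subject); the group-wise correlation blocks are stacked (group-major,
#' measure within group) and the stack is decomposed with SVD.  Permutation
#' reassigns behaviour rows relative to brain rows within group; the
#' bootstrap resamples subjects within group, recomputes the correlation
#' stack, and aligns each draw to the original saliences by orthogonal
#' Procrustes rotation.  Per group and LV, the correlation between brain
#' scores and each behaviour measure is reported with its bootstrap CI.
#'
#' @param brain numeric matrix, one row per subject (a single contrast per
#'   subject), e.g. a flattened [condition_contrast()].
#' @param behaviour data.frame with a `subject` column and the measure
#'   columns, one row per subject.
#' @param measures character vector of behaviour column names.
#' @param group per-subject group labels; defaults to the `"group"`
#'   attribute of `brain`.
#' @param n_perm,n_boot resampling sizes.
#' @param seed integer seed.
#' @param alpha CI level complement.
#' @param retry_cap maximum zero-variance bootstrap draws tolerated.
#' @return object of class `bpls_result`: singular values, design saliences
#'   (rows = group x measure), brain saliences, crossblock percentages,
#'   brain scores, `perm_p`, bootstrap SE/ratio/CI/reliability for the brain
#'   saliences, and `behav_corr` with `behav_corr_ci_lo/hi` (group x measure
#'   by LV).
#' @export
behavioural_pls <- function(brain, behaviour, measures,
                            group = attr(brain, "group"),
                            n_perm = 1000, n_boot = 1000, seed = NULL,
                            alpha = 0.05, retry_cap = 100) {
  stopifnot(is.matrix(brain), is.data.frame(behaviour),
            all(measures %in% names(behaviour)),
            "subject" %in% names(behaviour))
  subj <- rownames(brain)
  if (is.null(subj)) stop("brain matrix must have subject rownames")
  if (is.null(group)) stop("per-subject group labels are required")
  if (!is.null(names(group))) group <- unname(group[subj])
  stopifnot(length(group) == nrow(brain), !anyNA(group))
  behaviour <- behaviour[match(subj, behaviour$subject), , drop = FALSE]
  if (anyNA(behaviour$subject)) stop("behaviour table missing subject(s)")
  groups <- unique(unname(group))
  g_rows <- lapply(groups, function(g) which(group == g))
  names(g_rows) <- groups
  for (g in groups)
    if (length(g_rows[[g]]) < 3L) stop("need >= 3 subjects per group")
  B <- as.matrix(behaviour[, measures, drop = FALSE])

  R <- behav_corr_stack(B, brain, g_rows, measures)
  sfit <- svd_saliences(R$R)
  k <- length(sfit$d)
  scores <- brain %*% sfit$V
  rownames(scores) <- subj

  # observed per-group, per-measure correlation with each LV's brain scores
  bc <- lv_behav_corr(scores, B, g_rows, measures)

  # permutation: behaviour rows shuffled within group relative to brain
  obs <- sfit$d
  count <- numeric(k)
  withr::with_seed(if (is.null(seed)) NULL else derive_seed(seed, "bperm"), {
    for (b in seq_len(n_perm)) {
      Bp <- B
      for (g in groups) {
        rows <- g_rows[[g]]
        Bp[rows, ] <- B[rows[sample.int(length(rows))], , drop = FALSE]
      }
      dp <- svd(behav_corr_stack(Bp, brain, g_rows, measures)$R,
                nu = 0, nv = 0)$d
      count <- count + (dp >= obs - 1e-12)
    }
  })
  perm_p <- count / n_perm

  # bootstrap: subjects resampled within group
  p <- ncol(brain)
  Vdraws <- array(NA_real_, c(p, k, n_boot))
  bcdraws <- array(NA_real_, c(dim(bc), n_boot))
  n_retries <- 0L
  withr::with_seed(if (is.null(seed)) NULL else derive_seed(seed, "bboot"), {
    b <- 1L
    while (b <= n_boot) {
      take <- integer(0)
      for (g in groups) {
        rows <- g_rows[[g]]
        take <- c(take, rows[sample.int(length(rows), replace = TRUE)])
      }
      gb_rows <- split(seq_along(take), group[take])[groups]
      Bb <- B[take, , drop = FALSE]
      brb <- brain[take, , drop = FALSE]
      ok <- all(vapply(groups, function(g) {
        rows <- gb_rows[[g]]
        all(apply(Bb[rows, , drop = FALSE], 2, stats::sd) > 0) &&
          all(matrixStats_sd(brb[rows, , drop = FALSE]) > 0)
      }, TRUE))
      if (!ok) {
        n_retries <- n_retries + 1L
        if (n_retries > retry_cap)
          stop("bootstrap retry cap exceeded: zero-variance draw")
        next
      }
      sb <- svd_saliences(behav_corr_stack(Bb, brb, gb_rows, measures)$R)
      Q <- procrustes_rotation(sb$V[, seq_len(k), drop = FALSE], sfit$V)
      Vb <- sb$V[, seq_len(k), drop = FALSE] %*% Q
      Vdraws[, , b] <- Vb
      bcdraws[, , b] <- lv_behav_corr(brb %*% Vb, Bb, gb_rows, measures)
      b <- b + 1L
    }
  })
  out <- summarise_draws(Vdraws, sfit$V, alpha)
  bc_lo <- apply(bcdraws, c(1, 2), stats::quantile, probs = alpha / 2, type = 1)
  bc_hi <- apply(bcdraws, c(1, 2), stats::quantile, probs = 1 - alpha / 2,
                 type = 1)
  dimnames(bc_lo) <- dimnames(bc_hi) <- dimnames(bc)

  structure(list(
    singular_values = sfit$d,
    design_saliences = structure(sfit$U, dimnames = list(R$labels, NULL)),
    brain_saliences = structure(sfit$V,
                                dimnames = list(colnames(brain), NULL)),
    brain_scores = scores,
    crossblock_pct = crossblock_pct(sfit$d),
    corr_stack = R$R,
    perm_p = perm_p,
    boot_se = out$se, boot_ratio = out$ratio,
    boot_ci_lo = out$lo, boot_ci_hi = out$hi, reliable_mask = out$reliable,
    behav_corr = bc, behav_corr_ci_lo = bc_lo, behav_corr_ci_hi = bc_hi,
    n_retries = n_retries,
    settings = list(seed = seed, n_perm = as.integer(n_perm),
                    n_boot = as.integer(n_boot), alpha = alpha,
                    measures = measures, groups = groups)),
    class = "bpls_result")
}

behav_corr_stack <- function(B, brain, g_rows, measures) {
  blocks <- list(); labels <- character(0)
  for (g in names(g_rows)) {
    rows <- g_rows[[g]]
    sds <- c(apply(B[rows, , drop = FALSE], 2, stats::sd),
             matrixStats_sd(brain[rows, , drop = FALSE]))
    if (any(sds == 0))
      stop("zero-variance behaviour measure or brain column in group '",
           g, "'")
    blocks[[g]] <- stats::cor(B[rows, , drop = FALSE],
                              brain[rows, , drop = FALSE])
    labels <- c(labels, paste(g, measures, sep = ":"))
  }
  R <- do.call(rbind, blocks)
  rownames(R) <- labels
  list(R = R, labels = labels)
}

lv_behav_corr <- function(scores, B, g_rows, measures) {
  k <- ncol(scores)
  out <- matrix(NA_real_, length(g_rows) * length(measures), k)
  labels <- character(0)
  r <- 0L
  for (g in names(g_rows)) for (m in measures) {
    r <- r + 1L
    rows <- g_rows[[g]]
    out[r, ] <- suppressWarnings(
      stats::cor(B[rows, m], scores[rows, , drop = FALSE]))
    labels <- c(labels, paste(g, m, sep = ":"))
  }
  dimnames(out) <- list(labels, paste0("LV", seq_len(k)))
  out
}

# column SDs without extra dependencies
matrixStats_sd <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  sqrt(colSums((m - matrix(mu, n, ncol(m), byrow = TRUE))^2) / (n - 1))
}

#' @export
print.bpls_result <- function(x, ...) {
  cat("behavioural PLS (", x$settings$n_perm, " perms, ",
      x$settings$n_boot, " boots)\n", sep = "")
  for (i in seq_along(x$singular_values))
    cat(sprintf("  LV%d: sigma = %.4g, crossblock = %.1f%%, p = %.4g\n", i,
                x$singular_values[i], x$crossblock_pct[i], x$perm_p[i]))
  cat("behaviour-brain score correlations (LV1):\n")
  print(round(x$behav_corr[, 1, drop = FALSE], 3))
  invisible(x)
}
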