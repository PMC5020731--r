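#' Percentile summary of a score vector
#'
#' The 2.5th percentile, median, and 97.5th percentile, computed by linear
#' interpolation between order statistics (the type-7 convention); the
#' percentile definition is stated because conventions differ between
#' software packages.
#'
#' @param scores Numeric vector (at least 2 values).
#' @return Named numeric vector `c(p2.5, median, p97.5)`.
#' @export
percentile_summary <- function(scores) {
  if (length(scores) == 0L) stop("cannot summarise an empty score vector")
  q3(scores)
}

#' Subsampling null distribution for the larger group
#'
#' Repeatedly draws `n_small` *distinct* specimens without replacement from
#' the larger (post-transition) group and records the three percentile
#' statistics per axis, yielding the null distribution of each statistic at
#' the smaller group's sample size. This corrects for the strongly unequal
#' pre/post sample sizes: the pre-transition statistic is then positioned on
#' these histograms.
#'
#' @param post_scores Numeric matrix (or score data.frame from [project()])
#'   of the larger group's PC scores.
#' @param n_small Subsample size (the smaller group's n).
#' @param n_reps Number of replicates (default 10000).
#' @param seed Integer seed.
#' @param axes Integer vector of axis indices (default: all columns).
#' @param keep_indices Attach the `n_reps x n_small` matrix of drawn row
#'   indices as attribute `"indices"` (for auditing the without-replacement
#'   property).
#' @return List, one element per axis, each an `n_reps x 3` matrix with
#'   columns `p2.5`, `median`, `p97.5`.
#' @export
subsample_null <- function(post_scores, n_small, n_reps = 10000, seed = 1L,
                           axes = NULL, keep_indices = FALSE) {
  x <- score_matrix(post_scores)
  n <- nrow(x)
  if (n_small > n) {
    stop("n_small (", n_small, ") exceeds the available ", n, " specimens")
  }
  axes <- axes %||% seq_len(ncol(x))
  with_seed(seed, {
    out <- lapply(axes, function(a) {
      matrix(NA_real_, n_reps, 3,
             dimnames = list(NULL, c("p2.5", "median", "p97.5")))
    })
    names(out) <- colnames(x)[axes]
    idx_mat <- if (keep_indices) matrix(NA_integer_, n_reps, n_small)
    for (r in seq_len(n_reps)) {
      idx <- sample.int(n, n_small)
      if (keep_indices) idx_mat[r, ] <- idx
      for (k in seq_along(axes)) {
        out[[k]][r, ] <- q3(x[idx, axes[k]])
      }
    }
    if (keep_indices) attr(out, "indices") <- idx_mat
    out
  })
}

# Coerce a score container (matrix or data.frame from project()) to a plain
# numeric matrix of PC columns.
score_matrix <- function(scores) {
  if (is.matrix(scores)) return(scores)
  pc <- grep("^PC[0-9]+$", names(scores), value = TRUE)
  as.matrix(scores[pc])
}

#' Imputation-error interval for the pre-transition statistics
#'
#' Propagates the uncertainty of the missing-data estimation into the
#' pre-transition percentile statistics: each draw perturbs every imputed
#' cell by Gaussian noise at its cell SD (the regression residual SDs,
#' likelihood-averaged), re-applies the geometric-mean size adjustment,
#' projects onto the *fixed* morphospace, and recomputes the three
#' statistics. The interval is the central 95% of each statistic's draws.
#' With no imputed cells the interval degenerates to the point estimate.
#'
#' @param pre_imputed An `imputed_table` restricted to the pre-transition
#'   group (see [subset_period()]).
#' @param space The fitted `morphospace`.
#' @param n_draws Number of error draws (default 10000).
#' @param seed Integer seed.
#' @param axes Integer vector of axis indices (default: all).
#' @param mixture Passed to the error model (see [resample_imputations()]).
#' @return List with `point` (3 x n_axes matrix of point-estimate
#'   statistics), `lo` and `hi` (same shape: central-95% endpoints).
#' @export
pre_error_interval <- function(pre_imputed, space, n_draws = 10000,
                               seed = 1L, axes = NULL, mixture = FALSE) {
  base <- pre_imputed$table$values
  p <- ncol(base)
  axes <- axes %||% seq_len(p)
  stat_names <- c("p2.5", "median", "p97.5")
  axis_names <- colnames(space$loadings)[axes]

  point_scores <- project_matrix(space, adjust_matrix(base))
  point <- vapply(axes, function(a) q3(point_scores[, a]), numeric(3))
  dimnames(point) <- list(stat_names, axis_names)

  cells <- which(pre_imputed$imputed_mask)
  if (!length(cells)) {
    return(list(point = point, lo = point, hi = point, n_draws = n_draws))
  }
  if (mixture) {
    draws_list <- resample_imputations(pre_imputed, n_draws, seed = seed,
                                       mixture = TRUE)
    draws <- array(NA_real_, c(n_draws, 3, length(axes)))
    for (d in seq_len(n_draws)) {
      sc <- project_matrix(space, adjust_matrix(draws_list[[d]]))
      for (k in seq_along(axes)) draws[d, , k] <- q3(sc[, axes[k]])
    }
  } else {
    sds <- pre_imputed$cell_sd[cells]
    m <- length(cells)
    draws <- with_seed(seed, {
      arr <- array(NA_real_, c(n_draws, 3, length(axes)))
      for (d in seq_len(n_draws)) {
        x <- base
        x[cells] <- x[cells] + stats::rnorm(m, 0, sds)
        sc <- project_matrix(space, adjust_matrix(x))
        for (k in seq_along(axes)) arr[d, , k] <- q3(sc[, axes[k]])
      }
      arr
    })
  }
  lo <- apply(draws, c(2, 3), function(v) unname(q3(v)[1]))
  hi <- apply(draws, c(2, 3), function(v) unname(q3(v)[3]))
  dimnames(lo) <- dimnames(hi) <- list(stat_names, axis_names)
  list(point = point, lo = lo, hi = hi, n_draws = n_draws)
}

#' Compare pre- and post-transition score distributions
#'
#' Assembles the two resampling layers into the per-axis decision rule: for
#' each axis and each statistic (2.5th percentile, median, 97.5th
#' percentile), the pre-transition statistic's 95% imputation-error interval
#' is compared against the central 95% interval of the subsampled
#' post-transition statistic. `overlap` is `TRUE` iff the two intervals
#' intersect; an axis-level `shift_flag` fires only when *all three*
#' statistics are non-overlapping.
#'
#' @param pre_imputed `imputed_table` for the pre-transition group.
#' @param post_imputed `imputed_table` for the post-transition group (its
#'   point estimates are adjusted, projected and subsampled; imputation-error
#'   resampling is applied to the post group too only when
#'   `error_on_post = TRUE`, in which case its statistic interval replaces
#'   the point statistic check -- default mirrors the figure convention of
#'   error bars on the pre group only).
#' @param space Fitted `morphospace` (fixed; no refitting).
#' @param n_subsamples Subsampling replicates (default 10000).
#' @param n_error_draws Imputation-error draws (default 10000).
#' @param seed Integer seed; the subsampling layer uses `seed` and the error
#'   layer `seed + 1`.
#' @param axes Integer vector of axis indices to compare (default: all).
#' @param keep_draws Keep the per-replicate subsample statistics (for
#'   histogram plotting).
#' @return A `comparison_result`.
#' @export
compare_groups <- function(pre_imputed, post_imputed, space,
                           n_subsamples = 10000, n_error_draws = 10000,
                           seed = 1L, axes = NULL, keep_draws = FALSE,
                           error_on_post = FALSE) {
  n_pre <- nrow(pre_imputed$table$values)
  n_post <- nrow(post_imputed$table$values)
  if (n_pre == 0L || n_post == 0L) stop("both groups must be non-empty")
  if (n_post < n_pre) {
    stop("the post-transition group (n=", n_post, ") must be at least as ",
         "large as the pre-transition group (n=", n_pre, ")")
  }
  if (n_subsamples < 1 || n_error_draws < 1) stop("reps must be >= 1")
  if (n_subsamples == 1 || n_error_draws == 1) {
    warning("single-replicate resampling gives degenerate intervals")
  }
  p <- ncol(space$loadings)
  axes <- axes %||% seq_len(p)
  axis_names <- colnames(space$loadings)[axes]
  stat_names <- c("p2.5", "median", "p97.5")

  post_scores <- project_matrix(space, adjust_matrix(post_imputed$table$values))
  post_full <- vapply(axes, function(a) q3(post_scores[, a]), numeric(3))
  dimnames(post_full) <- list(stat_names, axis_names)

  null_draws <- subsample_null(post_scores, n_small = n_pre,
                               n_reps = n_subsamples, seed = seed,
                               axes = axes)
  post_lo <- vapply(null_draws, function(m) apply(m, 2, function(v) q3(v)[1]),
                    numeric(3))
  post_hi <- vapply(null_draws, function(m) apply(m, 2, function(v) q3(v)[3]),
                    numeric(3))
  dimnames(post_lo) <- dimnames(post_hi) <- list(stat_names, axis_names)

  pre_int <- pre_error_interval(pre_imputed, space, n_draws = n_error_draws,
                                seed = seed + 1L, axes = axes)
  pre_lo <- pre_int$lo
  pre_hi <- pre_int$hi
  if (error_on_post) {
    post_err <- pre_error_interval(post_imputed, space,
                                   n_draws = n_error_draws,
                                   seed = seed + 2L, axes = axes)
    # widen the post interval by the post group's own estimation error
    post_lo <- pmin(post_lo, post_err$lo)
    post_hi <- pmax(post_hi, post_err$hi)
  }

  overlap <- !(pre_hi < post_lo | post_hi < pre_lo)
  shift_flag <- apply(!overlap, 2, all)

  structure(
    list(axes = axes, axis_names = axis_names,
         pre_value = pre_int$point, pre_lo = pre_lo, pre_hi = pre_hi,
         post_value = post_full, post_lo = post_lo, post_hi = post_hi,
         overlap = overlap, shift_flag = shift_flag,
         n_pre = n_pre, n_post = n_post,
         n_subsamples = n_subsamples, n_error_draws = n_error_draws,
         seed = seed,
         null_draws = if (keep_draws) null_draws else NULL),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> pre n=%d, post n=%d; %d/%d reps\n",
              x$n_pre, x$n_post, x$n_subsamples, x$n_error_draws))
  for (k in seq_along(x$axis_names)) {
    cat(sprintf("  %s: shift_flag=%s (non-overlap: %s)\n",
                x$axis_names[k],
                x$shift_flag[k],
                paste(rownames(x$overlap)[!x$overlap[, k]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
as.data.frame.comparison_result <- function(x, ...) {
  stat_names <- rownames(x$overlap)
  rows <- expand.grid(statistic = stat_names, axis = x$axis_names,
                      stringsAsFactors = FALSE)[, c(2, 1)]
  data.frame(
    axis = rows$axis,
    statistic = rows$statistic,
    pre_value = as.vector(x$pre_value),
    pre_lo = as.vector(x$pre_lo),
    pre_hi = as.vector(x$pre_hi),
    post_value = as.vector(x$post_value),
    post_lo = as.vector(x$post_lo),
    post_hi = as.vector(x$post_hi),
    overlap = as.vector(x$overlap),
    shift_flag = rep(x$shift_flag, each = length(stat_names)),
    stringsAsFactors = FALSE)
}
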