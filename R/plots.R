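#' Scatter plot of the first two morphospace axes
#'
#' Pre-transition specimens in red, post-transition in blue, with group mean
#' crosses and a contour enclosing the 75% of each group's specimens closest
#' to its mean (an empirical highest-density region built from Mahalanobis
#' distance, drawn as the convex hull of the enclosed points).
#'
#' @param scores Score data.frame from [project()] (both periods).
#' @param file Optional PNG path; when `NULL`, draws on the active device.
#' @param axes Pair of axis indices to plot (default `c(1, 2)`).
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_morphospace <- function(scores, file = NULL, axes = c(1, 2)) {
  pc <- paste0("PC", axes)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 700)
    on.exit(grDevices::dev.off())
  }
  cols <- c(pre = "#cc3333", post = "#3355cc")
  graphics::plot(scores[[pc[1]]], scores[[pc[2]]],
                 col = cols[scores$period], pch = 19, cex = 0.6,
                 xlab = pc[1], ylab = pc[2],
                 main = "Morphospace: pre (red) vs post (blue)")
  for (per in c("pre", "post")) {
    sub <- scores[scores$period == per, pc, drop = FALSE]
    if (nrow(sub) < 3) next
    mu <- colMeans(sub)
    graphics::points(mu[1], mu[2], col = cols[per], pch = 3, cex = 2, lwd = 3)
    s <- stats::cov(sub)
    d <- stats::mahalanobis(sub, mu, s)
    core <- sub[d <= stats::quantile(d, 0.75, type = 7), , drop = FALSE]
    if (nrow(core) >= 3) {
      h <- grDevices::chull(core[[1]], core[[2]])
      graphics::polygon(core[h, 1], core[h, 2], border = cols[per])
    }
  }
  invisible(file)
}

#' Histogram panels of the subsampled post-transition statistics
#'
#' For one axis, draws the subsampling null distribution of each percentile
#' statistic with the pre-transition value as an arrow and its
#' imputation-error interval as a horizontal bar, mirroring the lower panels
#' of the group-comparison figures.
#'
#' @param result A `comparison_result` built with `keep_draws = TRUE`.
#' @param axis Index into the compared axes (default 1).
#' @param file Optional PNG path.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_comparison <- function(result, axis = 1, file = NULL) {
  if (is.null(result$null_draws)) {
    stop("comparison was built without keep_draws = TRUE")
  }
  draws <- result$null_draws[[axis]]
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 400)
    on.exit(grDevices::dev.off())
  }
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old), add = TRUE)
  stats_ <- colnames(draws)
  for (s in seq_along(stats_)) {
    pre_v <- result$pre_value[s, axis]
    xlim <- range(draws[, s], pre_v, result$pre_lo[s, axis],
                  result$pre_hi[s, axis])
    graphics::hist(draws[, s], breaks = 40, col = "#9db8e8",
                   border = NA, xlim = xlim, main = stats_[s],
                   xlab = result$axis_names[axis])
    usr <- graphics::par("usr")
    graphics::arrows(pre_v, usr[4] * 0.9, pre_v, usr[4] * 0.05,
                     col = "#cc3333", lwd = 2, length = 0.1)
    graphics::segments(result$pre_lo[s, axis], usr[4] * 0.05,
                       result$pre_hi[s, axis], usr[4] * 0.05,
                       col = "#cc3333", lwd = 3)
  }
  invisible(file)
}
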