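#' Discard specimens missing more than half of a partition's variables
#'
#' A specimen is removed when its fraction of missing variables is *strictly*
#' greater than `threshold` (so, with 7 variables, 4 or more missing cells
#' discard the row and 3 or fewer retain it). Surviving values are never
#' altered. Removal counts per period are attached as the `"filter_log"`
#' attribute.
#'
#' @param table A `measurement_table` restricted to one 7-variable partition.
#' @param threshold Missingness fraction in `[0, 1)` above which a specimen is
#'   discarded (default 0.5).
#' @return The filtered `measurement_table`.
#' @export
filter_incomplete <- function(table, threshold = 0.5) {
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1) {
    stop("threshold must lie in [0, 1)")
  }
  frac <- rowMeans(table$missing_mask)
  keep <- frac <= threshold
  log <- list(
    threshold = threshold,
    removed_pre = sum(!keep & table$period == "pre"),
    removed_post = sum(!keep & table$period == "post"),
    retained_pre = sum(keep & table$period == "pre"),
    retained_post = sum(keep & table$period == "post"))
  out <- subset_specimens(table, keep)
  attr(out, "filter_log") <- log
  out
}

#' Geometric-mean size adjustment
#'
#' Divides each specimen's measurements by that specimen's geometric mean,
#' yielding dimensionless shape variables whose per-row geometric mean is 1.
#' Computed in log space for numerical stability. The input must be complete
#' (imputation is applied first: the geometric mean needs all 7 values) and
#' strictly positive.
#'
#' @param table A complete `measurement_table` (no missing cells).
#' @return A `shape_table` (a `measurement_table` subclass of dimensionless
#'   values).
#' @export
size_adjust <- function(table) {
  if (any(table$missing_mask)) {
    stop("size_adjust requires a complete table; impute missing cells first")
  }
  vals <- adjust_matrix(table$values)
  out <- measurement_table(vals, table$specimen_id, table$region,
                           table$period, table$variable_codes,
                           sex = table$sex)
  class(out) <- c("shape_table", class(out))
  out
}

# Row-wise geometric-mean division on a plain positive matrix (fast path used
# inside resampling loops).
adjust_matrix <- function(values) {
  if (any(!is.finite(values) | values <= 0)) {
    stop("size adjustment requires strictly positive finite values")
  }
  lv <- log(values)
  exp(lv - rowMeans(lv))
}
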