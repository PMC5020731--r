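#' Fit a principal-component morphospace on pre-transition shape data
#'
#' Eigendecomposition of the covariance matrix (denominator `n - 1`) of the
#' size-adjusted pre-transition specimens. The centre is the pre-transition
#' mean; post-transition specimens are later positioned in this space by
#' [project()] without refitting. Variables are commensurate after geometric-
#' mean adjustment, so the covariance (not correlation) matrix is the
#' default; `correlation = TRUE` standardises each variable first.
#'
#' Signs of principal components are arbitrary in any eigendecomposition; a
#' deterministic convention is applied: within each column of loadings, the
#' entry of largest magnitude is made positive.
#'
#' @param pre_shapes A `shape_table` (or plain numeric matrix) of
#'   pre-transition specimens; must have more rows than variables.
#' @param correlation Use the correlation matrix instead of covariance.
#' @return A `morphospace`: `variable_codes`, `center`, `loadings`
#'   (orthonormal columns), `eigenvalues` (descending), `percent_variance`
#'   (sums to 100).
#' @export
fit_pca <- function(pre_shapes, correlation = FALSE) {
  x <- if (is.matrix(pre_shapes)) pre_shapes else pre_shapes$values
  codes <- if (is.matrix(pre_shapes)) {
    colnames(pre_shapes) %||% paste0("V", seq_len(ncol(pre_shapes)))
  } else pre_shapes$variable_codes
  if (anyNA(x)) stop("shape data must be complete before PCA")
  if (nrow(x) < ncol(x) + 1) {
    stop("need at least ", ncol(x) + 1, " specimens to fit a ",
         ncol(x), "-variable morphospace (got ", nrow(x), ")")
  }
  center <- colMeans(x)
  s <- stats::cov(x)
  scl <- rep(1, ncol(x))
  if (correlation) {
    scl <- sqrt(diag(s))
    s <- stats::cov2cor(s)
  }
  eig <- eigen(s, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  load <- eig$vectors
  # sign convention: largest-|entry| of each column positive
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(codes, paste0("PC", seq_along(lam)))
  structure(
    list(variable_codes = codes, center = center, loadings = load,
         eigenvalues = lam, percent_variance = 100 * lam / sum(lam),
         correlation = correlation, scale = scl),
    class = "morphospace")
}

#' @export
print.morphospace <- function(x, ...) {
  cat(sprintf("<morphospace> %d variables (%s)\n", length(x$variable_codes),
              paste(x$variable_codes, collapse = ", ")))
  cat("  % variance:",
      paste(sprintf("%.1f", x$percent_variance), collapse = " "), "\n")
  invisible(x)
}

# Internal fast path: scores for a plain matrix of shape rows.
project_matrix <- function(space, x) {
  x <- sweep(x, 2, space$center, `-`)
  if (isTRUE(space$correlation)) {
    # correlation-mode spaces are fitted on standardised variables
    x <- sweep(x, 2, space$scale, `/`)
  }
  x %*% space$loadings
}

#' Project specimens onto a fitted morphospace
#'
#' Computes `(x - center) %*% loadings` for every row: the post-transition
#' specimens are positioned in the pre-transition space using its loadings,
#' with no refitting. Projecting the fitting data reproduces the PCA's own
#' scores.
#'
#' @param space A `morphospace` from [fit_pca()].
#' @param shapes A `shape_table` with the space's variables in the same
#'   order.
#' @return A `data.frame` (`specimen_id`, `region`, `period`, `PC1`...`PCp`).
#' @export
project <- function(space, shapes) {
  x <- if (is.matrix(shapes)) shapes else shapes$values
  codes <- if (is.matrix(shapes)) colnames(x) else shapes$variable_codes
  if (!identical(as.character(codes), as.character(space$variable_codes))) {
    stop("variable mismatch: shapes have (", paste(codes, collapse = ", "),
         ") but the morphospace expects (",
         paste(space$variable_codes, collapse = ", "), ")")
  }
  scores <- project_matrix(space, x)
  if (is.matrix(shapes)) {
    return(as.data.frame(scores))
  }
  cbind(data.frame(specimen_id = shapes$specimen_id,
                   region = shapes$region,
                   period = shapes$period,
                   stringsAsFactors = FALSE),
        as.data.frame(scores))
}

#' Loading report with highlight flags
#'
#' Reports the loadings and percent variance of the leading components,
#' flagging loadings whose absolute value exceeds the highlight threshold
#' (the conventional |0.35| cut used when describing which measurements
#' define an axis).
#'
#' @param space A `morphospace`.
#' @param n_components Number of leading components to report (default 2).
#' @param highlight Absolute-loading threshold for the flag (default 0.35).
#' @return A long-format `data.frame` with columns `variable`, `component`,
#'   `loading`, `percent_variance`, `highlighted`.
#' @export
loading_report <- function(space, n_components = 2, highlight = 0.35) {
  p <- length(space$variable_codes)
  if (n_components > p) stop("n_components exceeds the number of variables")
  comps <- seq_len(n_components)
  data.frame(
    variable = rep(space$variable_codes, times = n_components),
    component = rep(paste0("PC", comps), each = p),
    loading = as.vector(space$loadings[, comps]),
    percent_variance = rep(space$percent_variance[comps], each = p),
    highlighted = as.vector(abs(space$loadings[, comps]) > highlight),
    stringsAsFactors = FALSE)
}
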