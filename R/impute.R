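#' Enumerate candidate predictor subsets for one target variable
#'
#' Every non-empty subset of the remaining variables is a candidate
#' regression, so a 7-variable partition yields 2^6 - 1 = 63 candidate
#' formulae per target. Order is deterministic: by subset size, then
#' lexicographic in the order of `variable_codes`.
#'
#' @param variable_codes Ordered character vector of Martin codes.
#' @param target The code whose missing values are to be estimated.
#' @return List of character vectors (predictor subsets).
#' @export
enumerate_formulae <- function(variable_codes, target) {
  if (!target %in% variable_codes) {
    stop("target '", target, "' not among the variable codes")
  }
  others <- setdiff(variable_codes, target)
  out <- list()
  for (k in seq_along(others)) {
    cmb <- utils::combn(others, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Fit one candidate imputation regression
#'
#' Ordinary least squares of `target` on `predictors`, using the rows complete
#' for the union of both. The residual standard deviation is the unbiased
#' estimate (degrees of freedom `n - k - 1`), floored at `sigma_floor` so a
#' perfect fit on a tiny complete-case set cannot capture infinite weight.
#' Candidates with fewer than `k + 2` complete cases or a rank-deficient
#' design are *rejected*: the function returns `NULL` rather than erroring,
#' mirroring the averaging over "all applicable formulae".
#'
#' @param table A `measurement_table` restricted to one region + partition.
#' @param target Target Martin code.
#' @param predictors Non-empty character vector of predictor codes.
#' @param sigma_floor Lower bound for the residual SD; defaults to
#'   `1e-8 * sd(observed target values)`.
#' @return A `regression_formula` (fields `target`, `predictors`, `intercept`,
#'   `coefficients`, `residual_sd`, `n_cases`) or `NULL` on rejection.
#' @export
fit_formula <- function(table, target, predictors, sigma_floor = NULL) {
  stopifnot(length(predictors) >= 1, !target %in% predictors)
  vals <- table$values
  if (is.null(sigma_floor)) {
    ts <- stats::sd(vals[, target], na.rm = TRUE)
    sigma_floor <- 1e-8 * (if (is.finite(ts) && ts > 0) ts else 1)
  }
  cols <- c(target, predictors)
  ok <- rowSums(is.na(vals[, cols, drop = FALSE])) == 0L
  n <- sum(ok)
  k <- length(predictors)
  if (n < k + 2) return(NULL)
  y <- vals[ok, target]
  x <- cbind(`(Intercept)` = 1, vals[ok, predictors, drop = FALSE])
  fit <- stats::lm.fit(x, y)
  if (fit$rank < ncol(x)) return(NULL)
  rss <- sum(fit$residuals^2)
  sigma <- sqrt(rss / (n - k - 1))
  structure(
    list(target = target, predictors = predictors,
         intercept = unname(fit$coefficients[1]),
         coefficients = fit$coefficients[-1],
         residual_sd = max(sigma, sigma_floor),
         n_cases = n),
    class = "regression_formula")
}

#' Likelihood weights over applicable formulae
#'
#' Each formula's weight is proportional to its per-observation Gaussian
#' likelihood at the fit, `exp(-log(sigma_f) - log(2*pi)/2 - 1/2)`, i.e.
#' proportional to `1 / sigma_f` where `sigma_f` is the residual SD. The
#' per-observation (rather than full-sample) convention keeps weights
#' comparable across formulae fitted on differing complete-case counts and
#' makes them invariant to global unit changes. Normalisation is done via
#' log-sum-exp.
#'
#' @param applicable Non-empty list of `regression_formula` objects.
#' @return Numeric weight vector summing to 1.
#' @export
formula_weights <- function(applicable) {
  if (!length(applicable)) stop("no applicable formulae to weight")
  ll <- -log(vapply(applicable, function(f) f$residual_sd, numeric(1)))
  m <- max(ll)
  w <- exp(ll - m)
  w / sum(w)
}

#' Estimate one missing cell from a specimen's preserved measurements
#'
#' Restricts the candidate set to the *applicable* formulae -- those whose
#' predictors are all observed in the row -- and returns the likelihood-
#' weighted average of their predictions. The cell's uncertainty is the
#' weight-averaged residual SD, used later for error resampling.
#'
#' @param row Named numeric vector (one specimen), `NA` where missing.
#' @param formulae List of candidate `regression_formula` objects for the
#'   target variable.
#' @param specimen_id Identifier used in the no-applicable-formula error.
#' @return List with `estimate` (mm), `sd` (mm), and `provenance` (per-formula
#'   predictors, weights, residual SDs and predictions).
#' @export
impute_cell <- function(row, formulae, specimen_id = "<unknown>") {
  observed <- names(row)[!is.na(row)]
  app <- formulae[vapply(formulae,
                         function(f) all(f$predictors %in% observed),
                         logical(1))]
  if (!length(app)) {
    stop("no applicable formula for specimen '", specimen_id,
         "': every candidate regression needs a missing predictor ",
         "(such rows should have been removed by the completeness filter)")
  }
  w <- formula_weights(app)
  preds <- vapply(app, function(f) {
    f$intercept + sum(f$coefficients * row[f$predictors])
  }, numeric(1))
  sds <- vapply(app, function(f) f$residual_sd, numeric(1))
  list(estimate = sum(w * preds),
       sd = sum(w * sds),
       provenance = list(
         predictors = lapply(app, function(f) f$predictors),
         weights = w, residual_sds = sds, predictions = preds))
}

#' Impute every missing cell of a measurement table
#'
#' Fits, once, all predictor-subset regressions for each target variable on
#' the pooled table (both periods of one region + partition: pooling
#' maximises complete cases), then estimates every missing cell as the
#' likelihood-weighted average over the formulae applicable to that specimen.
#' Fitting uses rows in sorted specimen-id order internally, so the result is
#' bitwise independent of input row order.
#'
#' @param table A `measurement_table`, already passed through
#'   [filter_incomplete()].
#' @param periods Periods whose rows form the fitting pool: `c("pre","post")`
#'   (default, pooled) or a single period for per-period fitting.
#' @return An `imputed_table`: the completed `table`, a `cell_sd` matrix (0
#'   for observed cells), an `imputed_mask`, per-cell `provenance`, and a
#'   rejection log.
#' @export
impute_table <- function(table, periods = c("pre", "post")) {
  vals <- table$values
  mask <- table$missing_mask
  codes <- table$variable_codes
  ord <- order(table$specimen_id)
  pool <- subset_specimens(table, ord[table$period[ord] %in% periods])

  cell_sd <- matrix(0, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  completed <- vals
  provenance <- list()
  rejected <- 0L
  fitted <- 0L

  for (j in which(colSums(mask) > 0L)) {
    target <- codes[j]
    ts <- stats::sd(pool$values[, target], na.rm = TRUE)
    sigma_floor <- 1e-8 * (if (is.finite(ts) && ts > 0) ts else 1)
    subsets <- enumerate_formulae(codes, target)
    fits <- lapply(subsets, function(p) {
      fit_formula(pool, target, p, sigma_floor = sigma_floor)
    })
    keep <- !vapply(fits, is.null, logical(1))
    rejected <- rejected + sum(!keep)
    fits <- fits[keep]
    fitted <- fitted + length(fits)
    if (!length(fits)) {
      stop("no candidate regression could be fitted for target '", target, "'")
    }
    # Applicable set and weights depend only on the row's observed pattern;
    # cache them so large tables do not re-filter 63 formulae per cell.
    pat_cache <- new.env(parent = emptyenv())
    for (i in which(mask[, j])) {
      row <- vals[i, ]
      key <- paste(which(!is.na(row)), collapse = ",")
      sel <- if (!is.null(pat_cache[[key]])) pat_cache[[key]] else {
        observed <- codes[!is.na(row)]
        s <- which(vapply(fits, function(f) all(f$predictors %in% observed),
                          logical(1)))
        pat_cache[[key]] <- s
        s
      }
      if (!length(sel)) {
        stop("no applicable formula for specimen '", table$specimen_id[i],
             "': every candidate regression needs a missing predictor")
      }
      app <- fits[sel]
      w <- formula_weights(app)
      preds <- vapply(app, function(f) {
        f$intercept + sum(f$coefficients * row[f$predictors])
      }, numeric(1))
      sds <- vapply(app, function(f) f$residual_sd, numeric(1))
      completed[i, j] <- sum(w * preds)
      cell_sd[i, j] <- sum(w * sds)
      provenance[[paste0(table$specimen_id[i], ":", target)]] <- list(
        specimen_id = table$specimen_id[i], variable = target,
        predictors = lapply(app, function(f) f$predictors),
        weights = w, residual_sds = sds, predictions = preds)
    }
  }
  out_table <- measurement_table(completed, table$specimen_id, table$region,
                                 table$period, codes, sex = table$sex)
  structure(
    list(table = out_table, cell_sd = cell_sd, imputed_mask = mask,
         provenance = provenance,
         fit_log = list(fitted = fitted, rejected = rejected,
                        pool_periods = periods)),
    class = "imputed_table")
}

#' @export
print.imputed_table <- function(x, ...) {
  cat(sprintf("<imputed_table> %d specimens x %d variables, %d imputed cells\n",
              nrow(x$table$values), ncol(x$table$values),
              sum(x$imputed_mask)))
  invisible(x)
}

#' Subset an imputed table by period
#'
#' @param imputed An `imputed_table`.
#' @param period `"pre"` or `"post"`.
#' @return An `imputed_table` restricted to the requested period.
#' @export
subset_period <- function(imputed, period = c("pre", "post")) {
  period <- match.arg(period)
  keep <- imputed$table$period == period
  structure(
    list(table = subset_specimens(imputed$table, keep),
         cell_sd = imputed$cell_sd[keep, , drop = FALSE],
         imputed_mask = imputed$imputed_mask[keep, , drop = FALSE],
         provenance = imputed$provenance,
         fit_log = imputed$fit_log),
    class = "imputed_table")
}

#' Resample imputation error
#'
#' Produces completed value matrices in which every imputed cell is replaced
#' by `estimate + Normal(0, cell_sd)`; observed cells are bitwise identical
#' across draws. With `mixture = TRUE` each draw instead picks one applicable
#' formula per cell with probability equal to its weight and adds noise at
#' that formula's own residual SD (a mixture draw rather than the averaged-SD
#' Gaussian).
#'
#' @param imputed An `imputed_table`.
#' @param n_draws Number of draws (at least 1).
#' @param seed Integer seed.
#' @param mixture Use the per-formula mixture draw instead of the averaged-SD
#'   Gaussian.
#' @return List of `n_draws` numeric matrices.
#' @export
resample_imputations <- function(imputed, n_draws, seed = 1L,
                                 mixture = FALSE) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  base <- imputed$table$values
  cells <- which(imputed$imputed_mask)
  m <- length(cells)
  if (m == 0L) {
    return(replicate(n_draws, base, simplify = FALSE))
  }
  sds <- imputed$cell_sd[cells]
  keys <- paste0(imputed$table$specimen_id[(cells - 1) %% nrow(base) + 1],
                 ":",
                 imputed$table$variable_codes[(cells - 1) %/% nrow(base) + 1])
  prov <- imputed$provenance[keys]
  with_seed(seed, {
    lapply(seq_len(n_draws), function(d) {
      x <- base
      if (mixture) {
        x[cells] <- vapply(prov, function(pv) {
          f <- sample.int(length(pv$weights), 1L, prob = pv$weights)
          pv$predictions[f] + stats::rnorm(1L, 0, pv$residual_sds[f])
        }, numeric(1))
      } else {
        x[cells] <- x[cells] + stats::rnorm(m, 0, sds)
      }
      x
    })
  })
}
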