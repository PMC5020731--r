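#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded package functions never
#' disturb the caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to run without seeding.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Fast type-7 (linear interpolation) quantiles at 2.5%, 50%, 97.5%.
# Equivalent to stats::quantile(x, c(.025, .5, .975), type = 7).
q3 <- function(x) {
  n <- length(x)
  if (n == 0L) stop("cannot summarise an empty score vector")
  xs <- sort.int(x, method = "quick")
  h <- (n - 1) * c(0.025, 0.5, 0.975)
  f <- floor(h)
  lo <- xs[f + 1]
  hi <- xs[pmin(f + 2, n)]
  out <- lo + (h - f) * (hi - lo)
  names(out) <- c("p2.5", "median", "p97.5")
  out
}

# Format a numeric vector so that read-back via as.numeric() is bitwise exact.
fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
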