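#' Specification for a synthetic craniometric dataset
#'
#' Describes the stochastic world the generator draws from: pre-transition
#' specimens are multivariate normal at `mean_pre` with covariance
#' `covariance`; post-transition specimens share the covariance but have their
#' mean shifted by `shift`. Missingness is applied completely at random
#' (MCAR) at `missing_rate`, capped per specimen so that no generated row
#' would be discarded by the completeness filter.
#'
#' @param n_pre,n_post Group sizes (each at least 3).
#' @param mean_pre Mean vector (mm) over the variables.
#' @param covariance Symmetric positive-definite covariance matrix (mm^2).
#' @param shift Vector (mm) added to the post-transition mean.
#' @param missing_rate MCAR missingness fraction in `[0, 1)`.
#' @param max_missing_per_specimen Maximum fraction of a specimen's variables
#'   allowed to be missing (default 3/7: below the 50% discard rule).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_pre, n_post, mean_pre, covariance,
                           shift = rep(0, length(mean_pre)),
                           missing_rate = 0,
                           max_missing_per_specimen = 3 / 7,
                           seed = 1L) {
  covariance <- as.matrix(covariance)
  p <- length(mean_pre)
  stopifnot(nrow(covariance) == p, ncol(covariance) == p,
            length(shift) == p)
  if (max(abs(covariance - t(covariance))) > 1e-8 * max(abs(covariance))) {
    stop("covariance matrix is not symmetric")
  }
  ch <- tryCatch(chol(covariance), error = function(e) NULL)
  if (is.null(ch)) stop("covariance matrix is not positive-definite")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (n_pre < 3 || n_post < 3) stop("n_pre and n_post must be >= 3")
  structure(
    list(n_pre = as.integer(n_pre), n_post = as.integer(n_post),
         mean_pre = mean_pre, covariance = covariance, chol = ch,
         shift = shift, missing_rate = missing_rate,
         max_missing_per_specimen = max_missing_per_specimen,
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

# Draw n multivariate-normal rows; rows containing a non-positive value are
# redrawn wholesale (not clipped) so the within-positive-orthant shape is
# preserved and geometric means stay defined.
rmvnorm_pos <- function(n, mu, ch) {
  p <- length(mu)
  draw <- function(m) {
    sweep(matrix(stats::rnorm(m * p), m, p) %*% ch, 2, mu, `+`)
  }
  x <- draw(n)
  bad <- which(apply(x, 1, function(r) any(r <= 0)))
  guard <- 0L
  while (length(bad)) {
    x[bad, ] <- draw(length(bad))
    bad <- bad[apply(x[bad, , drop = FALSE], 1, function(r) any(r <= 0))]
    guard <- guard + 1L
    if (guard > 1000L) stop("positivity redraw did not converge; ",
                            "means are too close to zero for this covariance")
  }
  x
}

#' Generate a synthetic craniometric dataset
#'
#' Draws pre- and post-transition specimens from the multivariate-normal world
#' described by `spec`, applies MCAR missingness with a per-specimen cap
#' (rows whose Bernoulli mask exceeds the cap are redrawn), and packages the
#' result as a [measurement_table()]. Identical spec and seed give bitwise
#' identical tables.
#'
#' @param spec A [synthetic_spec()].
#' @param variable_codes Martin codes for the columns (default: names of
#'   `spec$mean_pre`, falling back to the canonical vault set).
#' @param region Region label stamped on every specimen.
#' @return A `measurement_table` with `n_pre + n_post` rows.
#' @export
generate_dataset <- function(spec, variable_codes = NULL,
                             region = "Synthetica") {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- length(spec$mean_pre)
  variable_codes <- variable_codes %||% names(spec$mean_pre) %||%
    partition_codes("vault")[seq_len(p)]
  with_seed(spec$seed, {
    pre <- rmvnorm_pos(spec$n_pre, spec$mean_pre, spec$chol)
    post <- rmvnorm_pos(spec$n_post, spec$mean_pre + spec$shift, spec$chol)
    vals <- rbind(pre, post)
    n <- nrow(vals)
    if (spec$missing_rate > 0) {
      cap <- floor(spec$max_missing_per_specimen * p)
      mask <- matrix(stats::runif(n * p) < spec$missing_rate, n, p)
      over <- which(rowSums(mask) > cap)
      guard <- 0L
      while (length(over)) {
        mask[over, ] <- matrix(stats::runif(length(over) * p) <
                                 spec$missing_rate, length(over), p)
        over <- over[rowSums(mask[over, , drop = FALSE]) > cap]
        guard <- guard + 1L
        if (guard > 10000L) stop("missingness redraw did not converge")
      }
      vals[mask] <- NA_real_
    }
    measurement_table(vals,
                      specimen_id = sprintf("SYN-%04d", seq_len(n)),
                      region = region,
                      period = rep(c("pre", "post"),
                                   c(spec$n_pre, spec$n_post)),
                      variable_codes = variable_codes)
  })
}

#' Synthetic default vault parameters
#'
#' Plausible-magnitude mean vector and covariance matrix for the 7 vault
#' variables. These are *synthetic defaults* chosen to have the qualitative
#' structure the analysis assumes -- a dominant isometric size factor plus a
#' length-versus-breadth ("broadening") contrast factor carrying roughly half
#' of the shape variance -- and are not measurements of any real population.
#'
#' The covariance is built as `a a' + b b' + D`: `a` is the size-factor
#' loading (0.55 of each variable's SD), `b` the contrast-factor loading
#' (0.65 of SD, negative on the length variables M1 and M5, positive on the
#' breadth variables M8 and M11), and `D` a diagonal topping each variable up
#' to its marginal variance.
#'
#' @return `synthetic_vault_mean()`: named numeric vector (mm).
#'   `synthetic_vault_covariance()`: 7x7 positive-definite matrix (mm^2).
#'   `broadening_contrast()`: unit-norm contrast vector (negative on M1, M5;
#'   positive on M8, M11).
#' @export
synthetic_vault_mean <- function() {
  c(M1 = 182, M5 = 101, M8 = 139, M9 = 96, M11 = 123, M12 = 108, M17 = 134)
}

#' @rdname synthetic_vault_mean
#' @export
synthetic_vault_covariance <- function() {
  sd <- c(M1 = 6.2, M5 = 4.3, M8 = 5.4, M9 = 4.4, M11 = 5.1, M12 = 4.6,
          M17 = 5.0)
  cvec <- c(-1, -1, 1, 0, 1, 0, 0)
  a <- 0.55 * sd
  b <- 0.65 * sd * cvec
  d <- sd^2 - a^2 - b^2
  sigma <- outer(a, a) + outer(b, b) + diag(d)
  dimnames(sigma) <- list(names(sd), names(sd))
  sigma
}

#' @rdname synthetic_vault_mean
#' @export
broadening_contrast <- function() {
  w <- c(M1 = -1, M5 = -1, M8 = 1, M9 = 0, M11 = 1, M12 = 0, M17 = 0)
  w / sqrt(sum(w^2))
}

#' Canned simulation scenarios
#'
#' `ukraine_like_scenario()` mirrors the sample-size regime of the largest
#' real vault series (39 pre-transition versus 309 post-transition specimens)
#' and injects a mean shift along the broadening contrast -- positive on
#' maximum cranial breadth (M8) and biauricular breadth (M11), negative on
#' maximum cranial length (M1) and base length (M5) -- of magnitude
#' `shift_sd` within-group standard deviations along that contrast.
#' `null_scenario()` is identical but with zero shift.
#'
#' @param seed Integer seed.
#' @param shift_sd Shift magnitude in within-group SD units along the
#'   contrast (default 1).
#' @return A [synthetic_spec()].
#' @export
ukraine_like_scenario <- function(seed = 1L, shift_sd = 1) {
  mu <- synthetic_vault_mean()
  sigma <- synthetic_vault_covariance()
  w <- broadening_contrast()
  sd_along <- sqrt(drop(t(w) %*% sigma %*% w))
  synthetic_spec(n_pre = 39L, n_post = 309L,
                 mean_pre = mu, covariance = sigma,
                 shift = shift_sd * sd_along * w,
                 missing_rate = 0.1,
                 seed = seed)
}

#' @rdname ukraine_like_scenario
#' @export
null_scenario <- function(seed = 1L) {
  ukraine_like_scenario(seed = seed, shift_sd = 0)
}
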