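# Independent oracles. These deliberately re-derive results by the most
# literal route available (explicit normal equations, explicit subset
# enumeration, prcomp) and never call the code paths they check.

# OLS by explicit normal equations: solve(X'X) X'y.
oracle_ols <- function(x, y) {
  x <- cbind(1, as.matrix(x))
  if (qr(x)$rank < ncol(x)) return(NULL)
  beta <- solve(t(x) %*% x, t(x) %*% y)
  res <- y - x %*% beta
  list(beta = drop(beta), rss = sum(res^2))
}

# Brute-force likelihood-weighted subset-regression imputation of every NA
# cell of a plain matrix. Mirrors the documented conventions (per-observation
# likelihood => weight ~ 1/sigma; unbiased residual SD floored at
# 1e-8 * sd(target column); candidates rejected when complete cases < k + 2
# or the design is singular) through an entirely separate implementation.
oracle_impute_matrix <- function(vals) {
  p <- ncol(vals)
  out <- vals
  sds <- matrix(0, nrow(vals), p)
  for (j in seq_len(p)) {
    holes <- which(is.na(vals[, j]))
    if (!length(holes)) next
    ts <- stats::sd(vals[, j], na.rm = TRUE)
    floor_j <- 1e-8 * (if (is.finite(ts) && ts > 0) ts else 1)
    others <- setdiff(seq_len(p), j)
    # every non-empty subset of the other columns, via bitmask enumeration
    fits <- list()
    for (bits in seq_len(2^length(others) - 1)) {
      sel <- others[bitwAnd(bits, 2^(seq_along(others) - 1)) > 0]
      rows <- which(rowSums(is.na(vals[, c(j, sel), drop = FALSE])) == 0)
      k <- length(sel)
      if (length(rows) < k + 2) next
      fit <- oracle_ols(vals[rows, sel, drop = FALSE], vals[rows, j])
      if (is.null(fit)) next
      sigma <- max(sqrt(fit$rss / (length(rows) - k - 1)), floor_j)
      fits[[length(fits) + 1]] <- list(sel = sel, beta = fit$beta,
                                       sigma = sigma)
    }
    for (i in holes) {
      obs <- which(!is.na(vals[i, ]))
      app <- Filter(function(f) all(f$sel %in% obs), fits)
      stopifnot(length(app) > 0)
      inv <- vapply(app, function(f) 1 / f$sigma, numeric(1))
      w <- inv / sum(inv)
      preds <- vapply(app, function(f) {
        f$beta[1] + sum(f$beta[-1] * vals[i, f$sel])
      }, numeric(1))
      out[i, j] <- sum(w * preds)
      sds[i, j] <- sum(w * vapply(app, function(f) f$sigma, numeric(1)))
    }
  }
  list(values = out, cell_sd = sds)
}

# Random small imputable table: masks are capped at <= half the variables per
# row so every hole keeps at least one applicable single-predictor formula.
random_holed_matrix <- function(seed, n_max = 12, p_max = 4) {
  set.seed(seed)
  n <- sample(8:n_max, 1)
  p <- sample(3:p_max, 1)
  mu <- runif(p, 50, 150)
  a <- runif(p, 0.5, 2)
  size <- rnorm(n, 0, 5)
  vals <- sweep(outer(size, a), 2, mu, `+`) + matrix(rnorm(n * p, 0, 1.5), n, p)
  cap <- floor(p / 2)
  mask <- matrix(runif(n * p) < 0.15, n, p)
  over <- rowSums(mask) > cap
  while (any(over)) {
    mask[over, ] <- matrix(runif(sum(over) * p) < 0.15, sum(over), p)
    over <- rowSums(mask) > cap
  }
  vals[mask] <- NA_real_
  colnames(vals) <- paste0("M", seq_len(p))
  vals
}

# Raw-space shift multiplier along the broadening contrast that produces a
# post-minus-pre displacement of `target` pooled SDs along PC1 of the
# pre-transition shape morphospace (the units in which the power criterion
# states its effect size). Estimated once from the generator's own population
# parameters at large n under a fixed seed.
calibrate_pc1_shift <- function(target = 1.5, n = 5000, seed = 42) {
  mu <- synthetic_vault_mean()
  sig <- synthetic_vault_covariance()
  unit <- ukraine_like_scenario(seed = seed, shift_sd = 1)$shift
  big <- synthetic_spec(n, n, mu, sig, shift = unit, seed = seed)
  shp <- size_adjust(generate_dataset(big))
  pre <- shp$values[shp$period == "pre", ]
  post <- shp$values[shp$period == "post", ]
  space <- fit_pca(pre)
  s_pre <- project(space, pre)[, "PC1"]
  s_post <- project(space, post)[, "PC1"]
  target * stats::sd(s_pre) / abs(mean(s_post) - mean(s_pre))
}
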