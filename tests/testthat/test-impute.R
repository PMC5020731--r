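test_that("formula enumeration is complete and deterministically ordered", {
  expect_equal(enumerate_formulae(c("A", "B", "C"), "A"),
               list("B", "C", c("B", "C")))
  expect_length(enumerate_formulae(partition_codes("vault"), "M8"), 63)
  expect_equal(enumerate_formulae(c("A", "B"), "B"), list("A"))
  expect_error(enumerate_formulae(c("A", "B"), "Z"), "Z")

  # ordering: subset size first, then lexicographic in variable order
  subs <- enumerate_formulae(c("M1", "M5", "M8", "M9"), "M9")
  expect_equal(lengths(subs), c(1, 1, 1, 2, 2, 2, 3))
  expect_equal(subs[[4]], c("M1", "M5"))
  expect_equal(subs[[6]], c("M5", "M8"))
})

test_that("fit_formula matches the normal-equations oracle and rejects", {
  # exact relation y = 2x + 1: perfect fit, residual SD at the floor
  x <- c(80, 90, 100, 110, 120)
  tab <- make_table(cbind(A = 2 * x + 1, B = x), codes = c("A", "B"))
  f <- fit_formula(tab, "A", "B")
  expect_equal(f$intercept, 1, tolerance = 1e-8)
  expect_equal(unname(f$coefficients), 2, tolerance = 1e-10)
  expect_equal(f$residual_sd, 1e-8 * sd(2 * x + 1), tolerance = 1e-6)
  expect_equal(f$n_cases, 5L)

  # random 8-row table vs explicit (X'X)^{-1} X'y
  set.seed(41)
  vals <- toy_matrix(8, 4, seed = 41)
  colnames(vals) <- c("A", "B", "C", "D")
  tab <- make_table(vals, codes = colnames(vals))
  f <- fit_formula(tab, "A", c("B", "D"))
  orc <- oracle_ols(vals[, c("B", "D")], vals[, "A"])
  expect_equal(f$intercept, unname(orc$beta[1]), tolerance = 1e-8)
  expect_equal(unname(f$coefficients), unname(orc$beta[-1]),
               tolerance = 1e-8)
  expect_equal(f$residual_sd, sqrt(orc$rss / (8 - 2 - 1)), tolerance = 1e-8)

  # too few complete cases: 3 predictors need >= 5 rows
  small <- make_table(toy_matrix(4, 4, seed = 2),
                      codes = c("A", "B", "C", "D"))
  expect_null(fit_formula(small, "A", c("B", "C", "D")))

  # rank-deficient design rejected, zero complete cases rejected
  collin <- vals; collin[, "D"] <- 3 * collin[, "B"]
  expect_null(fit_formula(make_table(collin, codes = colnames(vals)),
                          "A", c("B", "D")))
  holed <- vals; holed[, "B"] <- NA
  expect_null(fit_formula(make_table(holed, codes = colnames(vals)),
                          "A", c("B")))
})

test_that("likelihood weights follow the 1/sigma convention", {
  mk <- function(sd) structure(list(target = "A", predictors = "B",
                                    intercept = 0, coefficients = c(B = 1),
                                    residual_sd = sd, n_cases = 10L),
                               class = "regression_formula")
  expect_equal(formula_weights(list(mk(0.7))), 1)
  expect_equal(formula_weights(list(mk(2), mk(2))), c(0.5, 0.5))
  expect_equal(formula_weights(list(mk(1), mk(2))), c(2 / 3, 1 / 3))
  expect_error(formula_weights(list()), "no applicable")

  # invariant under a global unit change (mm -> cm scales every sigma)
  sds <- c(0.8, 1.7, 3.1)
  expect_equal(formula_weights(lapply(sds, mk)),
               formula_weights(lapply(sds / 10, mk)))
})

test_that("impute_cell averages predictions by weight", {
  mk <- function(sd, b0) structure(
    list(target = "A", predictors = "B", intercept = b0,
         coefficients = c(B = 0), residual_sd = sd, n_cases = 10L),
    class = "regression_formula")
  # sds (1, 3) -> weights (0.75, 0.25); predictions 10 and 12 -> 10.5
  cell <- impute_cell(c(A = NA, B = 100), list(mk(1, 10), mk(3, 12)))
  expect_equal(cell$estimate, 10.5)
  expect_equal(cell$sd, 0.75 * 1 + 0.25 * 3)
  expect_equal(sum(cell$provenance$weights), 1, tolerance = 1e-12)

  # a formula with enormous residual SD is effectively ignored
  cell2 <- impute_cell(c(A = NA, B = 100),
                       list(mk(1, 10), mk(3, 12), mk(1e16, 1e6)))
  expect_lt(abs(cell2$estimate - cell$estimate), 1e-9)

  # no applicable formula: the only candidate needs a missing predictor
  needs_c <- structure(list(target = "A", predictors = "C", intercept = 0,
                            coefficients = c(C = 1), residual_sd = 1,
                            n_cases = 10L), class = "regression_formula")
  expect_error(impute_cell(c(A = NA, B = 1, C = NA), list(needs_c), "SPC-9"),
               "SPC-9")
})

test_that("impute_table: identity, perfect-information limit, invariants", {
  # complete table passes through untouched
  vals <- toy_matrix(10, 4, seed = 9)
  colnames(vals) <- c("A", "B", "C", "D")
  tab <- make_table(vals, codes = colnames(vals))
  imp <- impute_table(tab)
  expect_identical(imp$table$values, tab$values)
  expect_true(all(imp$cell_sd == 0))

  # exact noiseless linear system: withheld truth recovered
  set.seed(55)
  z <- runif(12, 50, 150)
  exact <- cbind(A = z, B = 2 * z + 5, C = 0.5 * z + 30)
  truth <- exact[4, "B"]
  exact[4, "B"] <- NA
  imp <- impute_table(make_table(exact, codes = colnames(exact)))
  expect_equal(imp$table$values[4, "B"], unname(truth), tolerance = 1e-6)

  # observed cells exact; weights in provenance sum to 1 within 1e-12
  vals2 <- random_holed_matrix(77)
  tab2 <- make_table(vals2, codes = colnames(vals2))
  imp2 <- impute_table(tab2)
  expect_identical(imp2$table$values[!tab2$missing_mask],
                   vals2[!tab2$missing_mask])
  expect_true(all(imp2$cell_sd[!tab2$missing_mask] == 0))
  expect_true(all(imp2$cell_sd[tab2$missing_mask] > 0))
  for (pv in imp2$provenance) {
    expect_equal(sum(pv$weights), 1, tolerance = 1e-12)
  }

  # row-order invariance: permuted input gives identical imputations
  perm <- sample(nrow(vals2))
  tabp <- make_table(vals2[perm, , drop = FALSE], codes = colnames(vals2),
                     ids = sprintf("T-%03d", seq_len(nrow(vals2)))[perm])
  impp <- impute_table(tabp)
  expect_identical(impp$table$values[order(perm), ], imp2$table$values)

  # global rescaling: estimates scale, weights unchanged
  tabs <- make_table(vals2 / 10, codes = colnames(vals2))
  imps <- impute_table(tabs)
  expect_equal(imps$table$values, imp2$table$values / 10,
               tolerance = 1e-10)
  k <- names(imp2$provenance)[1]
  expect_equal(imps$provenance[[k]]$weights, imp2$provenance[[k]]$weights,
               tolerance = 1e-10)
})

test_that("error resampling perturbs only imputed cells, reproducibly", {
  vals <- random_holed_matrix(88)
  imp <- impute_table(make_table(vals, codes = colnames(vals)))
  cells <- which(imp$imputed_mask)
  obs <- which(!imp$imputed_mask)

  draws <- resample_imputations(imp, 100, seed = 6)
  expect_length(draws, 100)
  for (d in draws[c(1, 50, 100)]) {
    expect_identical(d[obs], imp$table$values[obs])
  }
  # reproducible from seed; different seed differs
  again <- resample_imputations(imp, 100, seed = 6)
  expect_identical(draws, again)
  other <- resample_imputations(imp, 100, seed = 7)
  expect_false(identical(draws, other))

  # all cell_sd zero -> every draw equals the point-estimate table
  clean <- impute_table(make_table(toy_matrix(8, 3, seed = 1),
                                   codes = c("A", "B", "C")))
  for (d in resample_imputations(clean, 5, seed = 1)) {
    expect_identical(d, clean$table$values)
  }

  # mixture mode runs and also leaves observed cells alone
  mix <- resample_imputations(imp, 20, seed = 3, mixture = TRUE)
  expect_identical(mix[[20]][obs], imp$table$values[obs])
  expect_error(resample_imputations(imp, 0, seed = 1), ">= 1")
})

test_that("imputation beats column means on correlated MCAR data", {
  # single-replicate sanity check (the 20-replicate version is acceptance)
  spec <- synthetic_spec(300, 3, synthetic_vault_mean(),
                         synthetic_vault_covariance(), seed = 12)
  truth <- generate_dataset(spec)$values[1:300, ]
  set.seed(91)
  mask <- matrix(runif(300 * 7) < 0.15, 300, 7)
  mask[rowSums(mask) > 3, ] <- FALSE
  holed <- truth; holed[mask] <- NA
  tab <- make_table(holed, codes = colnames(truth))
  imp <- impute_table(tab)
  rmse_w <- sqrt(mean((imp$table$values[mask] - truth[mask])^2))
  colm <- colMeans(holed, na.rm = TRUE)
  rmse_m <- sqrt(mean((matrix(colm, 300, 7, byrow = TRUE)[mask] -
                       truth[mask])^2))
  expect_lt(rmse_w, rmse_m)
})
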