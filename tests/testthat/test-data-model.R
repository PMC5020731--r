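test_that("registry contains the 15 codes and resolves both partitions", {
  reg <- martin_registry()
  expect_setequal(reg$martin_code,
                  c("M1", "M5", "M8", "M9", "M11", "M11b", "M12", "M17",
                    "M40", "M45", "M48", "M51", "M52", "M54", "M55"))
  expect_equal(anyDuplicated(reg$martin_code), 0L)
  expect_length(partition_codes("vault"), 7)
  expect_length(partition_codes("face"), 7)
  expect_equal(partition_codes("vault"),
               c("M1", "M5", "M8", "M9", "M11", "M12", "M17"))
  expect_equal(partition_codes("vault", region = "Levant"),
               c("M1", "M5", "M8", "M9", "M11b", "M12", "M17"))
  expect_equal(partition_codes("face"),
               c("M40", "M45", "M48", "M51", "M52", "M54", "M55"))
})

test_that("read_measurements parses blanks as mask and validates input", {
  df <- data.frame(specimen_id = c("A", "B", "C"),
                   region = "Ukraine", period = c("pre", "pre", "post"),
                   M1 = c(180.5, 179, 185), M17 = c(132, NA, 130))
  tab <- read_measurements(write_fixture_csv(df))
  expect_s3_class(tab, "measurement_table")
  expect_equal(n_specimens(tab), 3L)
  expect_equal(sum(tab$missing_mask), 1L)
  expect_true(tab$missing_mask["B", "M17"])

  # literal "NA" also read as missing
  p <- tempfile(fileext = ".csv")
  writeLines(c("specimen_id,region,period,M1,M17",
               "A,Ukraine,pre,180.5,NA",
               "B,Ukraine,post,179,130"), p)
  expect_equal(sum(read_measurements(p)$missing_mask), 1L)

  dup <- df; dup$specimen_id <- c("UKR-001", "UKR-001", "C")
  expect_error(read_measurements(write_fixture_csv(dup)), "UKR-001")

  neg <- df; neg$M1[2] <- -3
  expect_error(read_measurements(write_fixture_csv(neg)), "B.*M1")

  badper <- df; badper$period[1] <- "transitional"
  expect_error(read_measurements(write_fixture_csv(badper)), "transitional")

  extra <- df; extra$museum <- "X"
  expect_warning(read_measurements(write_fixture_csv(extra)), "museum")

  sexed <- df; sexed$sex <- c("F", "M", "F")
  expect_equal(read_measurements(write_fixture_csv(sexed))$sex,
               c("F", "M", "F"))
})

test_that("read -> write -> read round trip is exact", {
  set.seed(31)
  vals <- matrix(runif(40, 60, 190), 8, 5)
  vals[cbind(c(2, 5, 7), c(1, 4, 3))] <- NA
  tab <- make_table(vals, period = rep(c("pre", "post"), each = 4),
                    codes = c("M1", "M5", "M8", "M9", "M11"))
  p <- tempfile(fileext = ".csv")
  write_measurements(tab, p)
  back <- read_measurements(p)
  expect_identical(back$values, tab$values)
  expect_identical(back$missing_mask, tab$missing_mask)
  expect_identical(back$specimen_id, tab$specimen_id)
  expect_identical(back$period, tab$period)
  expect_identical(back$region, tab$region)
})

test_that("select_partition picks canonical columns and the Levant M11b", {
  set.seed(7)
  codes <- c(partition_codes("vault"), "M11b", "M40")
  vals <- matrix(runif(9 * 18, 80, 200), 18, 9, dimnames = list(NULL, codes))
  tab <- make_table(vals, period = rep(c("pre", "post"), 9),
                    region = rep(c("Ukraine", "Levant"), each = 9),
                    codes = codes)

  ukr <- select_partition(tab, element = "vault", region = "Ukraine")
  expect_equal(ukr$variable_codes, partition_codes("vault"))
  expect_true(all(ukr$region == "Ukraine"))

  lev <- select_partition(tab, element = "vault", region = "Levant")
  expect_equal(lev$variable_codes,
               c("M1", "M5", "M8", "M9", "M11b", "M12", "M17"))

  # values are never altered, and the operation is idempotent
  expect_identical(ukr$values,
                   tab$values[tab$region == "Ukraine", partition_codes("vault")])
  again <- select_partition(ukr, element = "vault", region = "Ukraine")
  expect_identical(again$values, ukr$values)

  expect_error(select_partition(tab, element = "face"), "M45")
})

test_that("score and report writers round-trip and count correctly", {
  scores <- data.frame(specimen_id = c("A", "B"), region = "R",
                       period = c("pre", "post"),
                       PC1 = c(0.123456789123456789, -2e-17),
                       PC2 = c(pi, exp(1)))
  p <- tempfile(fileext = ".csv")
  write_scores(scores, p)
  back <- read_scores(p)
  expect_identical(back$PC1, scores$PC1)
  expect_identical(back$PC2, scores$PC2)

  empty <- scores[0, ]
  write_scores(empty, p)
  expect_equal(nrow(read_scores(p)), 0L)
  expect_equal(length(readLines(p)), 1L)  # header only

  # report: 2 axes x 3 statistics -> 6 rows
  spec <- synthetic_spec(10, 20, c(A = 100, B = 120, C = 90),
                         diag(c(9, 16, 4)), seed = 5)
  tab <- generate_dataset(spec, variable_codes = c("A", "B", "C"))
  imp <- impute_table(tab)
  shp <- size_adjust(subset_period(imp, "pre")$table)
  space <- fit_pca(shp)
  cmp <- compare_groups(subset_period(imp, "pre"), subset_period(imp, "post"),
                        space, n_subsamples = 50, n_error_draws = 50,
                        seed = 1, axes = 1:2)
  rp <- tempfile(fileext = ".csv")
  write_report(cmp, rp)
  expect_equal(nrow(utils::read.csv(rp)), 6L)
})
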