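#' Construct a measurement table
#'
#' The central data container: a specimens-by-variables matrix of linear
#' cranial measurements in millimetres, with specimen identifiers, region and
#' period (pre/post agricultural transition) labels, and a missingness mask.
#' Missing cells are `NA` in `values`; the mask is stored explicitly so that
#' downstream stages (imputation, error resampling) can distinguish observed
#' from estimated cells after completion.
#'
#' @param values Numeric matrix, one row per specimen, `NA` where missing.
#'   Observed entries must be strictly positive and finite.
#' @param specimen_id Character vector of unique specimen identifiers.
#' @param region Character vector (recycled if length 1) of region labels.
#' @param period Character vector (recycled if length 1); each element must be
#'   `"pre"` or `"post"`.
#' @param variable_codes Martin codes naming the columns, in canonical order.
#' @param sex Optional character passthrough column (not used analytically).
#' @return An object of class `measurement_table`.
#' @export
measurement_table <- function(values, specimen_id, region, period,
                              variable_codes = colnames(values), sex = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (is.null(variable_codes)) {
    stop("variable_codes must be supplied when `values` has no column names")
  }
  if (length(variable_codes) != ncol(values)) {
    stop("variable_codes length does not match the number of columns")
  }
  specimen_id <- as.character(specimen_id)
  if (length(specimen_id) != n) stop("specimen_id length != number of rows")
  dup <- specimen_id[duplicated(specimen_id)]
  if (length(dup)) {
    stop("duplicate specimen_id: ", paste(unique(dup), collapse = ", "))
  }
  region <- rep_len(as.character(region), n)
  period <- rep_len(as.character(period), n)
  bad_period <- setdiff(unique(period), c("pre", "post"))
  if (length(bad_period)) {
    stop("unknown period label(s): ", paste(bad_period, collapse = ", "),
         " (must be 'pre' or 'post')")
  }
  obs <- !is.na(values)
  bad <- obs & (!is.finite(values) | values <= 0)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-positive or non-finite measurement for specimen '%s', variable '%s'",
      specimen_id[idx[1]], variable_codes[idx[2]]))
  }
  dimnames(values) <- list(specimen_id, variable_codes)
  structure(
    list(values = values,
         missing_mask = is.na(values),
         specimen_id = specimen_id,
         region = region,
         period = period,
         variable_codes = as.character(variable_codes),
         sex = if (!is.null(sex)) rep_len(as.character(sex), n) else NULL),
    class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  cat(sprintf("<%s> %d specimens x %d variables (%s)\n",
              class(x)[1], nrow(x$values), ncol(x$values),
              paste(x$variable_codes, collapse = ", ")))
  cat(sprintf("  periods: pre=%d post=%d | regions: %s | missing cells: %d\n",
              sum(x$period == "pre"), sum(x$period == "post"),
              paste(unique(x$region), collapse = ", "),
              sum(x$missing_mask)))
  invisible(x)
}

#' Number of specimens in a table
#' @param table A `measurement_table`.
#' @return Integer count of rows.
#' @export
n_specimens <- function(table) nrow(table$values)

#' Subset specimens (rows) of a measurement table
#'
#' Row subset preserving all parallel fields (labels, mask, sex passthrough).
#'
#' @param table A `measurement_table`.
#' @param keep Logical or integer row index.
#' @return A `measurement_table` with the selected specimens.
#' @export
subset_specimens <- function(table, keep) {
  measurement_table(table$values[keep, , drop = FALSE],
                    table$specimen_id[keep],
                    table$region[keep],
                    table$period[keep],
                    table$variable_codes,
                    sex = if (!is.null(table$sex)) table$sex[keep] else NULL)
}

#' Read a craniometric measurement table from CSV
#'
#' Expects a header row with `specimen_id`, `region`, `period`, and any number
#' of Martin-code measurement columns. Blank cells and the literal string
#' `"NA"` both denote missing values. Columns that are neither required
#' metadata, a registered Martin code, nor the optional `sex` passthrough are
#' ignored with a warning.
#'
#' @param path Path to a UTF-8 CSV file.
#' @param registry Variable registry, as from [martin_registry()].
#' @return A [measurement_table()].
#' @export
read_measurements <- function(path, registry = martin_registry()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("", "NA"))
  required <- c("specimen_id", "region", "period")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("input file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  known <- intersect(names(df), registry$martin_code)
  unknown <- setdiff(names(df), c(required, registry$martin_code, "sex"))
  if (length(unknown)) {
    warning("ignoring unrecognised column(s): ",
            paste(unknown, collapse = ", "))
  }
  if (!length(known)) stop("no Martin-code measurement columns found")
  vals <- as.matrix(df[known])
  storage.mode(vals) <- "double"
  measurement_table(vals, df$specimen_id, df$region, df$period,
                    variable_codes = known,
                    sex = if ("sex" %in% names(df)) df$sex else NULL)
}

#' Write a measurement table to CSV
#'
#' Values are written at full double precision (17 significant digits) so that
#' a read/write/read round trip preserves measurements, mask and labels
#' exactly. Missing cells are written as empty strings.
#'
#' @param table A `measurement_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  out <- data.frame(specimen_id = table$specimen_id,
                    region = table$region,
                    period = table$period,
                    stringsAsFactors = FALSE)
  if (!is.null(table$sex)) out$sex <- table$sex
  for (j in seq_along(table$variable_codes)) {
    out[[table$variable_codes[j]]] <- fmt_full(table$values[, j])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Restrict a table to one anatomical partition (and optionally one region)
#'
#' Selects the 7 canonical variables of the requested cranial element in
#' canonical order. For `region = "Levant"` the vault set substitutes M11b
#' (biradicular breadth) for M11, reflecting the different inferior vault
#' breadth methodology of that material. When `region` is given, rows are also
#' restricted to that region. Cell values are never altered.
#'
#' @param table A `measurement_table`.
#' @param registry Variable registry (used for code validation).
#' @param element `"vault"` or `"face"`.
#' @param region Optional region label.
#' @return A `measurement_table` with exactly 7 variable columns.
#' @export
select_partition <- function(table, registry = martin_registry(),
                             element = c("vault", "face"), region = NULL) {
  element <- match.arg(element)
  codes <- partition_codes(element, region)
  absent <- setdiff(codes, table$variable_codes)
  if (length(absent)) {
    stop(sprintf("table lacks required %s column(s)%s: %s", element,
                 if (is.null(region)) "" else paste0(" for region ", region),
                 paste(absent, collapse = ", ")))
  }
  keep <- if (is.null(region)) rep(TRUE, nrow(table$values)) else
    table$region == region
  if (!any(keep)) stop("no specimens found for region ", region)
  sub <- subset_specimens(table, keep)
  measurement_table(sub$values[, codes, drop = FALSE],
                    sub$specimen_id, sub$region, sub$period,
                    variable_codes = codes, sex = sub$sex)
}

#' Write and read principal component score tables
#'
#' Scores are written at full double precision so round trips are exact.
#'
#' @param scores A data.frame with `specimen_id`, `region`, `period` and
#'   numeric score columns (`PC1`, `PC2`, ...).
#' @param path File path.
#' @return `write_scores` returns `path` invisibly; `read_scores` returns the
#'   score data.frame.
#' @export
write_scores <- function(scores, path) {
  out <- scores
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- fmt_full(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = "")
  for (nm in grep("^PC[0-9]+$", names(df), value = TRUE)) {
    df[[nm]] <- as.numeric(df[[nm]])
  }
  df
}

#' Write a group-comparison report to CSV
#'
#' One row per axis and percentile statistic, carrying the pre-transition
#' point value, its imputation-error interval, the central 95% interval of the
#' subsampled post-transition statistic, and the overlap and axis-level shift
#' flags.
#'
#' @param result A `comparison_result`, as from [compare_groups()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  df <- as.data.frame(result)
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) out[[nm]] <- fmt_full(out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
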