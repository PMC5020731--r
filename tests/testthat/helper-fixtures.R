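# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except the packaged registry.

# Quick measurement_table from a (possibly NA-holed) matrix.
make_table <- function(values, period = "pre", region = "Testland",
                       codes = NULL, ids = NULL) {
  values <- as.matrix(values)
  codes <- codes %||% colnames(values) %||%
    partition_codes("vault")[seq_len(ncol(values))]
  ids <- ids %||% sprintf("T-%03d", seq_len(nrow(values)))
  measurement_table(values, ids, region, period, variable_codes = codes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Correlated positive toy data: latent size factor plus noise.
toy_matrix <- function(n, p, seed, base = 100, sd_size = 6, sd_noise = 2) {
  set.seed(seed)
  size <- rnorm(n, 0, sd_size)
  base + outer(size, seq(0.8, 1.2, length.out = p)) +
    matrix(rnorm(n * p, 0, sd_noise), n, p)
}

# Small measurement CSV on disk; returns the path.
write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
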