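# cranioshift

Did a population's cranial shape change across the Neolithic transition?
`cranioshift` answers that question from standard linear craniometric
measurements (Martin variables, in mm) of pre- and post-transition specimens,
under the two constraints that dominate real archaeological series: most
crania are incomplete, and the two groups are strongly unequal in size
(e.g. 39 pre- vs 309 post-transition vaults).

The package is aimed at biological anthropologists and morphometricians
working with legacy craniometric databases, and at anyone who needs a tested
reference implementation of likelihood-weighted regression imputation
("WaverR"-style) and resampled percentile group comparison.

## The method

For one region and one cranial element (vault: M1, M5, M8, M9, M11, M12,
M17 — with M11b replacing M11 for Levantine material; face: M40, M45, M48,
M51, M52, M54, M55):

1. **Completeness filter.** Specimens missing strictly more than 50% of the
   element's 7 variables are discarded.
2. **Imputation.** For each target variable *y*, every non-empty subset *S*
   of the remaining 6 variables defines a candidate OLS regression
   `y ~ X_S` (63 per target), fitted on complete cases. A missing cell is
   estimated as the likelihood-weighted average over the *applicable*
   formulae (those whose predictors the specimen preserves):
   `ŷ = Σ_f w_f ŷ_f` with `w_f ∝ exp(ℓ̄_f) ∝ 1/σ̂_f`, where `σ̂_f` is the
   unbiased residual SD. The cell's uncertainty is `Σ_f w_f σ̂_f`.
3. **Size adjustment.** Each specimen's values are divided by its own
   geometric mean, giving dimensionless shape variables with per-row GM = 1.
4. **Morphospace.** A PCA (covariance matrix, n−1) is fitted on the
   pre-transition shapes only; post-transition specimens are projected with
   the pre-transition loadings — no refitting.
5. **Comparison.** Per PC axis, the 2.5th percentile, median and 97.5th
   percentile are compared through two resampling layers: the larger (post)
   group is subsampled without replacement down to the smaller group's size
   10,000 times (the null histograms), and the pre-transition statistics get
   a 95% interval from 10,000 imputation-error draws
   (`estimate + N(0, cell_sd)` in every imputed cell, re-adjusted and
   re-projected). An axis is flagged as shifted only when **all three**
   statistics' intervals fail to overlap.

A synthetic-data module generates multivariate-normal measurement tables
with a localized mean shift, MCAR missingness and the unequal group sizes
above, so the whole pipeline is testable without any restricted museum data.

## Worked example

A synthetic "Ukraine-like" vault series: 39 pre vs 309 post specimens, 10%
MCAR missingness, and a broadening shift (breadths M8/M11 up, lengths M1/M5
down) of 1.5 within-group SD along that contrast:

```r
library(cranioshift)

spec <- ukraine_like_scenario(seed = 2024, shift_sd = 1.5)
tab  <- generate_dataset(spec)
tab
#> <measurement_table> 348 specimens x 7 variables (M1, M5, M8, M9, M11, M12, M17)
#>   periods: pre=39 post=309 | regions: Synthetica | missing cells: 252

res <- run_analysis(run_config(synthetic = spec, n_subsamples = 2000,
                               n_error_draws = 2000, seed = 7, axes = 1:2))
subset(res$loading_report, component == "PC1")
#>   variable component     loading percent_variance highlighted
#> 1       M1       PC1 -0.51880572           48.478        TRUE
#> 2       M5       PC1 -0.27856496           48.478       FALSE
#> 3       M8       PC1  0.62573109           48.478        TRUE
#> 4       M9       PC1 -0.22150773           48.478       FALSE
#> 5      M11       PC1  0.45209416           48.478        TRUE
#> 6      M12       PC1  0.04501171           48.478       FALSE
#> 7      M17       PC1 -0.07887928           48.478       FALSE

res$comparison
#> <comparison_result> pre n=39, post n=309; 2000/2000 reps
#>   PC1: shift_flag=TRUE (non-overlap: p2.5, median, p97.5)
#>   PC2: shift_flag=FALSE (non-overlap: )
```

Reading the output: PC1 carries 48% of the pre-transition shape variance and
contrasts cranial breadths (M8, M11: positive loadings, highlighted at the
conventional |0.35| cut) against lengths (M1: negative) — the classic
brachycephalisation axis. The post-transition group sits higher on PC1 than
the pre-transition group on all three percentile statistics, outside both
the subsampling null intervals and the pre group's imputation-error
intervals, so the axis-level shift flag fires. PC2 overlaps on every
statistic: no shift is claimed there.

The same pipeline runs on real CSV data
(`run_config(input = "my_table.csv", region = "Ukraine", element = "vault",
seed = 1)`); input files need `specimen_id`, `region`, `period`
(`pre`/`post`) and Martin-code columns, with blanks for missing cells.

There is also a command-line interface (see `?cli_main`):

```sh
Rscript inst/cli/cranioshift.R run --config config.json --out-dir results/
```

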