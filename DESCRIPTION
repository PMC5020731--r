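Package: cranioshift
Title: Craniometric Shape Change Across the Neolithic Transition
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for detecting shifts in cranial shape between
    pre- and post-agricultural-transition populations from linear craniometric
    measurements (Martin variables). Implements likelihood-weighted regression
    imputation of missing measurements over all predictor subsets, per-specimen
    geometric-mean size adjustment, principal component morphospaces fitted on
    pre-transition specimens with projection of post-transition specimens, and
    a double-resampling comparison of 2.5th percentile, median and 97.5th
    percentile score statistics with overlap flags. A synthetic-data generator
    emulating the multivariate-normal measurement structure, unequal group
    sizes and specimen-level missingness of museum craniometric series makes
    every stage testable without access to restricted collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
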