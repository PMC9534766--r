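Package: rvsat
Title: Set-Based Rare-Variant Association Tests with Ultra-Rare Variant Collapsing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene- and region-based rare-variant association testing for
    biobank-style case-control and quantitative phenotypes. Collapses
    ultra-rare variants (minor allele count at or below a configurable
    threshold, default 10) into a single marker before testing, and runs
    Burden, SKAT and SKAT-O score tests with saddlepoint adjustment for
    case-control imbalance. Tests are performed over a grid of maximum
    minor-allele-frequency cutoffs and functional-annotation masks and
    aggregated per gene with the Cauchy combination, falling back to
    minimum-p Bonferroni when any cell p-value is unity. Includes a
    two-step null-model layer (plain GLM, covariates-as-offset mode, and a
    sparse genetic-relationship-matrix mixed model with variance-ratio
    calibration) and a simulation framework for type-I-error and power
    studies on synthetic exome-like genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    readr,
    withr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
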