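Package: goftscan
Title: Goodness-of-Fit Association Scans for Common and Rare Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Window-based association testing of sets of common and rare
    genetic variants against quantitative or binary traits using the
    Berk-Jones goodness-of-fit statistic on per-variant p-values. Provides
    fixed-width genome segmentation, collapsing of rare variants between
    adjacent common variants by genotype summation, permutation-based
    empirical p-values, p-value-level meta-analysis across data sources
    (for example merging array-based p-values into sequencing windows),
    and a simulation engine for evaluating type-I error and power.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
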