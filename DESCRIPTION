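Package: pleiocond
Title: Cross-Trait Conditional and Conjunctional FDR Analysis of GWAS
    Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying shared genetic architecture between pairs of
    complex traits from GWAS summary statistics: harmonization and filtering of
    summary-statistics tables, conditional quantile-quantile enrichment,
    conditional and conjunctional false discovery rate (condFDR/conjFDR)
    statistics computed from an empirical two-dimensional lookup with
    LD-informed random pruning, FUMA-style genomic risk-locus definition with
    lead/independent-significant/candidate SNP hierarchies, effect-direction
    concordance, positional gene mapping with over-representation tests, and LD
    score regression estimates of SNP heritability and genetic correlation. A
    bivariate causal-mixture simulator with block LD and optional sample
    overlap provides ground truth for calibration studies of false-discovery
    control and power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
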