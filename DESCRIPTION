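Package: inflectr
Title: Growth-Curve Inflection Analytics and Digital Gene Expression Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the joint analysis of sigmoid animal growth curves and
    stage-contrast digital gene expression (DGE) tag profiling, built around
    the three developmental stages defined by a growth curve's inflection
    point (before, under and after it). Fits logistic, Gompertz and Von
    Bertalanffy models by multi-start nonlinear least squares and derives
    inflection age, inflection weight and maximum daily gain in closed form
    and numerically; normalizes tag counts to RPKM and computes expressed
    transcript sets, abundance concentration, saturation curves and replicate
    correlations; calls differentially expressed genes with a conditional
    exact count test and conjunctive p-value and fold-change thresholds;
    scores gene-set over-representation with the EASE modified Fisher
    statistic under Benjamini-Hochberg correction; classifies stage-specific
    genes against QTL intervals and tests per-chromosome enrichment; and
    quantifies qPCR results by the 2^-ddCt method and relative mtDNA copy
    number by 2^dCt. A synthetic-data generator reproduces the statistical
    structure of every input so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
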