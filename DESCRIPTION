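Package: mirstem
Title: Quantitative Analysis of miRNA-Driven Mammary Stem Cell Biology
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable analysis toolkit for quantifying how a miRNA family shapes
    the mammary stem-cell compartment. Implements qPCR miRNA profiling from raw
    cycle-threshold tables (detection filtering, housekeeping-median delta-Ct
    normalization, differential calling, Fisher overlap tests), cohort
    stratification by miRNA signatures (Ward clustering of standardized
    expression with chi-square contingency analysis), detection of de-repressed
    direct miRNA targets from ranked fold-change profiles (equal-count binning,
    observed-versus-expected enrichment, cross-experiment consensus and target
    intersection), tumor-initiating-cell frequency estimation from limiting
    dilution assays under the single-hit Poisson model, and four-parameter
    logistic dose-response fitting with relative potency estimation. A synthetic
    data generator with planted ground truth emulates every input, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
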