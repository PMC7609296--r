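Package: varcohort
Title: Cohort-Scale Variant Spectrum, Constraint and Pharmacogenomic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for population-scale whole-genome sequencing
    cohorts: variant normalization and site quality control, allele-frequency
    spectrum classes and per-sample metrics, Hardy-Weinberg exact testing,
    a miniature consequence engine with per-gene observed/potential
    loss-of-function (OP) ratios and site-frequency-spectrum estimates of the
    fraction of variants under purifying selection, context-dependent
    tolerance scoring (CDTS) of sliding genomic windows from heptamer
    mutation-tolerance tables, CPIC-style star-allele diplotyping with
    metabolizer phenotypes and the pharmacogenetic warfarin dosing algorithm,
    polygenic risk score construction with stratified group testing, and
    population-structure estimators (LD pruning, PCA, Hudson Fst, PLINK-style
    IBD/PI_HAT relatedness). A synthetic-cohort generator produces every
    input with the statistical structure the analyses assume, so the whole
    pipeline is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    IRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    seqinr,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
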