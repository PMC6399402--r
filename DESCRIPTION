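Package: rarescan
Title: Gene-Centered Rare-Variant Association Scans for Case-Control
    Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A genome-wide, gene-centered strategy for testing the
    aggregate effect of rare variation (MAF < 1%) on a binary phenotype in
    imputed case-control cohorts.  Provides post-genotyping and
    post-imputation quality control, minor-allele accounting and
    rare-variant categorization, principal-component and genomic-control
    stratification correction, linkage-disequilibrium pruning to an
    independent marker set (r2 < 0.1), per-gene logistic burden tests and
    the sequence kernel association test (SKAT), pooled-marker permutation
    multiple-testing correction, intersection-based candidate selection,
    and a resampling test for enrichment of gene-disease annotations.  A
    synthetic-cohort generator with population structure, a rare-skewed
    site frequency spectrum, linkage-disequilibrium blocks and spiked
    per-gene effects makes every stage testable without access to
    controlled genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
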