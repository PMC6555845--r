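Package: urvburden
Title: Ultra-Rare Variant Burden Analysis for Case-Control Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control analysis of ultra-rare coding variants (URVs) in
    severe neurodevelopmental disease cohorts. Partitions cohort variants by
    allele count after external-database exclusion, applies per-chromosome
    zygosity rules and Grubbs outlier QC, classifies variants into a
    functional taxonomy (null, consensus-damaging missense, splice-region and
    DNase-hypersensitive-site synonymous), and tests per-individual burden
    with covariate-adjusted logistic regression, gene-based collapsing tests
    with permutation gene-set overlap, a per-gene Poisson model of de novo
    mutation enrichment, tissue-expression enrichment ranking, and power
    calculation for logistic burden tests. Includes a synthetic cohort
    generator with ground-truth bookkeeping for calibration and recovery
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
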