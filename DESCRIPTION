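Package: epicontext
Title: Chromatin Accessibility Context, Evolutionary Constraint and
    Cross-Disease GWAS Signal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studying how shifting chromatin
    accessibility context (fetal to adult development, young to old
    adulthood) modulates evolutionary constraint and disease-risk
    associations of regulatory variants. Provides peak consolidation and
    empirical-Bayes moderated differential-accessibility calling, nested
    young/old contrasts with a directionality-sharing test, permutation
    enrichment of region sets against randomized genomic backgrounds,
    per-region conservation summaries, cross-disease per-variant
    aggregation of GWAS summary statistics, hypergeometric enrichment of
    strong variants near region sets, promoter-capture gene linking, and
    cross-disease gene-locus rank aggregation with permutation gene-set
    tests. A synthetic-data generator with planted ground truth exercises
    every stage end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    jsonlite,
    withr
Config/testthat/edition: 3
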