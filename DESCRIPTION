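Package: epivariant
Title: Individual-Specific Chromatin Outlier Detection in Case-Control
    ChIP-seq Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects rare, individual-specific alterations of
    promoter-associated H3K4me3 signal in case-control ChIP-seq cohorts.
    Provides promoter-anchored library normalization, per-peak
    normalized-coverage quantification, per-case outlier calling against the
    full control panel, recurrence and sample-correlation summaries,
    one-tailed Fisher enrichment of annotation categories, gene sets and
    GWAS-derived region sets with Bonferroni and Benjamini-Hochberg control,
    and a seeded synthetic-cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
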