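Package: openwas
Title: Openness-Weighted Association Scans for GWAS Segment Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aggregates predicted per-SNP chromatin-openness effects into
    individual-level segment openness scores and tests segment-phenotype
    association either from individual genotypes or from GWAS summary
    statistics combined with a linkage-disequilibrium (LD) reference panel.
    Provides TSS-anchored regulatory-region segmentation, allele
    harmonization of openness weight tables, a peak-resampling enrichment
    test, an LD-aware z-score simulator with openness-rank-stratified
    heritability, type-I-error and heritability-enrichment evaluation
    harnesses, and a synthetic fixture generator so the whole pipeline runs
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
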