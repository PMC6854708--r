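Package: idaseq
Title: Individualized Differential Expression for Matched Tumor Trios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-patient paired differential expression for cohorts of matched
    adjacent-normal / primary-tumor / metastasis (PVTT) samples without
    replicates. Pools adjacent-normal tissues to estimate measurement variance
    conditional on expression mean, tests each patient's primary/PVTT pair with
    a z-statistic derived from that trend (BH-adjusted within patient), and
    attaches a one-sided permutation FDR to genes recurrently called across
    patients. Also provides an integrative candidate-driver screen (gene-level
    copy-number dosage and promoter-methylation Spearman correlations,
    hypermethylated-promoter calling, chromosome-arm enrichment), arm-level CNV
    recurrence summaries, cohort heterogeneity distances, and a synthetic
    matched-trio multi-omics generator with ground truth for validating the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
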