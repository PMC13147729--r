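Package: spermage
Title: Age-Related DNA Methylation Analysis in Sperm on 450K-Style Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end epigenome-wide association pipeline for
    age-related DNA methylation changes in sperm measured on Illumina
    450K-style arrays. Provides beta/M-value transformation, probe-level
    quality filters, per-CpG linear modelling of M-values on age with
    empirical-Bayes variance moderation, Benjamini-Hochberg FDR control,
    methylation-subgroup classification (unmethylated, hemi-methylated,
    fully methylated), intercept-method back-transformation of M-scale
    effects to the beta scale, mapping of differentially methylated CpGs
    to imprinted genes and imprint control regions, cross-study gene
    overlap counting, and a multi-criteria "score of interest" for
    biomarker candidate selection. A calibrated synthetic-array generator
    with planted age effects makes every stage testable without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
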