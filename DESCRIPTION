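Package: modscape
Title: Comparative Transcriptomics of Fumarate Compounds in Astrocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Differential expression with empirical-Bayes moderated t-statistics,
    reference-guided co-expression module discovery with variable-height dendrogram
    pruning, directional gene-signature concordance and cumulative-overlap area
    statistics, disease-gene and GWAS-locus proximity resampling tests, promoter
    motif scanning with spline-adjusted logistic enrichment models, and small-sample
    validation statistics (exact Wilcoxon rank-sum, delta-delta-Ct, Fisher's LSD
    letter groupings). Includes a synthetic-data generator with planted ground truth
    emulating a four-treatment (control plus three fumarate esters) astrocyte
    microarray experiment, so every stage of the pipeline is exercisable and testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
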