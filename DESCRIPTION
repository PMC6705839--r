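Package: nrcrosstalk
Title: Pathway-Level Cross-Talk Analysis for Multi-Treatment Transcriptomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying gene-level and pathway-level
    cross-talk between nuclear-receptor ligand treatments in a multi-condition
    transcriptomic design. Implements probe-to-gene collapsing by maximal
    variance, per-time-point linear models with treatment-versus-pooled-control
    contrasts and empirical-Bayes moderated t-statistics, weighted
    Kolmogorov-Smirnov gene-set enrichment with a sample-permutation null and
    leading-edge extraction, and disjoint multi-treatment overlap partitions
    with category summaries. A synthetic-data generator with machine-readable
    ground truth supports parameter-recovery and error-rate validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    withr,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: GeneExpression, DifferentialExpression, GeneSetEnrichment,
    Microarray, Pathways
RoxygenNote: 7.3.3
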