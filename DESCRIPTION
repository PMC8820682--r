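Package: regenmir
Title: miRNA Time-Course Analysis of Ethanol-Impaired Liver Regeneration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for NanoString-style miRNA count data from a
    two-diet (chronic ethanol vs pair-fed carbohydrate control) rat partial
    hepatectomy time course. Provides TMM scaling-factor normalization and the
    log2 counts-per-million transform with optional mean-variance precision
    weights, per-miRNA linear models with empirical-Bayes moderated t
    statistics, COMPACT discretized trajectory pattern counting between
    conditions, Pearson correlation screening against a reference miRNA
    (miR-21), weighted Kolmogorov-Smirnov signature enrichment of liver
    nonparenchymal cell-type miRNA sets with permutation nulls, and delta-delta
    CT relative quantification of qPCR data. A negative-binomial synthetic-data
    generator emulates the full study design with recorded ground truth so
    every stage is testable without the deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    fgsea,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
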