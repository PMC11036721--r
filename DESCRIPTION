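Package: trajectomics
Title: Trajectory-Pattern Analysis of Multi-Class Time-Course Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of bulk whole-transcriptome time courses sampled as one
    pooled library per timepoint across several RNA classes (mRNA, lncRNA,
    circRNA, miRNA). Provides negative-binomial differential expression
    between adjacent timepoints without replicates, encoding of per-gene
    dynamics as up/down/maintained (U/D/M) pattern strings with ranked
    frequency tables and pattern-space coverage statistics, normalization
    (size factors, CPM, TPM, FPKM) and abundance binning, confidence-filtered
    interaction-network construction with dense-module extraction and a
    twelve-measure hub-gene consensus, competing-endogenous-RNA network
    assembly through shared miRNAs, hypergeometric over-representation
    analysis against user-supplied gene sets, and a synthetic-data generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    MASS,
    stats,
    utils,
    fgsea,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
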