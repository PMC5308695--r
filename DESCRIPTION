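Package: ampliscan
Title: Amplicon Panel Read Simulation, Alignment, Variant Filtering and
    Dosage-Quotient Copy-Number Analysis
Version: 0.1.0
Authors@R:
    person("ampliscan", "developers", email = "ampliscan@example.org",
           role = c("aut", "cre"))
Description: Toolkit for multiplex-PCR amplicon panel sequencing of the
    BRCA1/BRCA2 type: a two-stage read mapper (BWT key seeding followed by
    Smith-Waterman local alignment with a linear rearrangement rescoring
    pass and primer soft-clipping), a variant caller with the homopolymer
    error filter cascade designed for ion semiconductor data (depth test,
    insertion overrun, deletion displacement, HP percentage, strand bias),
    exon-level copy-number detection from per-amplicon read counts via
    within-multiplex dosage quotients, and a read simulator that models
    restriction-enzyme fragmentation (MseI/Csp6I/FspBI), platform error
    profiles, spiked variants, copy-number events and FFPE-style
    admixtures so that every stage can be tested without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    data.table,
    jsonlite,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics,
    Rsamtools,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
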