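Package: telorep
Title: Telomere Terminal-Permutation Profiling and Heterochromatin
    Re-Replication Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for four desk-scale computations used in plant
    telomere biology: classification of the terminal telomeric-repeat
    permutation of blunt-ended chromosome termini from hairpin-ligation
    amplicon reads; genome-wide re-replication scoring from binned,
    mappability-filtered read depth with base-window scaling; flow-cytometry
    endoreduplication peak fitting with a chi-square peak-normality statistic
    and re-replication shoulder quantification; and densitometric
    normalization chains for G-overhang in-gel and telomere dot-blot signals.
    Includes seeded synthetic-data generators that emulate each input with
    known ground truth so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, Coverage, FlowCytometry, CopyNumberVariation
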