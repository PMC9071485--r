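Package: TailDynamics
Title: Poly(A) Tail Calling, mRNA Decay Kinetics and Time-Course Gene-Set
    Analysis for Naive-to-Formative Transitions
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying mRNA poly(A) tail dynamics from aligned
    long-read (CCS) data and relating them to mRNA turnover during stem-cell
    state transitions. Extracts 3' soft-clipped poly(A) tails from SAM
    alignments with upstream A-tract correction, classifies and filters tail
    calls, and summarises per-gene tail lengths as geometric means. Estimates
    first-order mRNA decay rates and half-lives from transcription-shutoff
    time courses, performs 2^-ddCt relative quantification, and processes
    expression time courses (TPM, threshold-based differential calls,
    sign-pattern temporal clustering, PCA) with an auditable gene-set ledger
    recording every intersection, union and exclusion. Includes seeded
    simulators with truth tables for every stage so the whole pipeline is
    verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
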