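Package: runonSig
Title: Protocol Signatures and Quality Metrics for Run-On Sequencing Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quality-control statistics and protocol-signature analysis for
    nascent transcription run-on sequencing libraries (GRO-seq and PRO-seq).
    Implements formula-defined library QC metrics (promoter-proximal pausing
    index, exon/intron contamination ratio, genic/intergenic read ratio,
    short-read TSS ratio, positional nucleotide composition, library-prep
    sequence signatures, library complexity), a single-level symlet-5 discrete
    wavelet transform of normalized per-gene coverage with per-gene principal
    component scores, a linear support vector machine protocol classifier
    evaluated by leave-one-out cross-validation with majority-rules voting,
    a mechanistic simulator of run-on reads near transcription start sites
    with biotin-NTP termination and exponential size selection, TSS-anchored
    metagene profiles, and a seeded synthetic cohort generator with
    controllable protocol and library-prep signatures.
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
    Biostrings,
    rtracklayer,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, QualityControl, Transcription, GeneRegulation,
    Classification, Coverage
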