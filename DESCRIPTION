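Package: uvmotif
Title: UV Damage, Repair and Mutation Analysis at Transcription Factor
    Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Dissects how UV-induced cyclobutane pyrimidine dimer (CPD)
    formation and nucleotide excision repair jointly shape the somatic
    mutation rate at transcription factor binding sites. Provides
    motif scanning inside ChIP-seq peaks with DHS-based activity calls,
    strand-aware stacking of 2001-bp windows around motif centers,
    trinucleotide/pentanucleotide background mutation models, relative
    repair inference from fixed-depth two-timepoint damage maps,
    tetranucleotide-matched within-motif dipyrimidine nulls, prediction
    of late-timepoint damage, and a self-contained synthetic study
    generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
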