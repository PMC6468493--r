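Package: dsbtx
Title: Nascent RNA Polymerase II Transcription at Sequence-Specific DNA
    Double-Strand Breaks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for nascent transcription at
    restriction-endonuclease-induced DNA double-strand breaks (DSBs). The
    package locates AsiSI recognition sites (GCGATCGC) in a genome and
    annotates them against gene models, converts paired-end mNET-seq
    alignments into strand-specific single-nucleotide RNA polymerase II
    3'-end profiles, classifies sites as cut or uncut from gammaH2A.X/H2A.X
    ChIP log2 ratios, builds gene-oriented sense/antisense metagene profiles
    with rolling-average smoothing and a proximal/distal break-transcription
    statistic, and quantifies DSB induction from qPCR Ct tables with the
    double-normalized delta-delta-Ct method. A synthetic-data module
    generates toy genomes, alignments, ChIP tracks and Ct tables with known
    ground truth so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    GenomeInfoDb,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
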