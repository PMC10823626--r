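Package: flicsim
Title: Simulation and Analysis of Concatemer Long-Read Isoform Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico workbench for concatemer-based long-read isoform
    sequencing (MAS-seq / Iso-Seq style libraries). Generates synthetic
    spike-in transcriptomes with known isoform structure, simulates cDNA
    synthesis with template-switching artifacts, length-dependent capture
    loss, two-fraction size selection, barcode-directed dimer/tetramer
    concatenation and HiFi read errors; then splits concatemer reads at
    barcode junctions into segmented reads, refines them to full-length
    non-concatemer reads, collapses them into supported isoform clusters,
    assigns SQANTI3-style structural categories, and computes spike-in
    recall, replicate concordance, length-bias, differential-expression
    and fusion-artifact metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
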