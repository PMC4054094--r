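Package: covbias
Title: Depth-of-Coverage Bias Analysis and DNA-Isolation Artifact Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read-depth analysis pipeline for quantifying and correcting
    systematic coverage biases in low-pass whole-genome sequencing and
    aCGH-style data. Partitions a reference genome into windows of fixed
    accessible (non-repeat, non-gap) content or fixed genomic span, counts
    aligned reads per window, and normalizes by reads-per-million, random
    downsampling, or cross-sample quantile normalization. Corrects GC bias
    by per-window normalization against the median count of the windows
    with most similar GC content, computes coverage-evenness and
    tissue-difference metrics, segments log2 ratio tracks into regions of
    differential apparent copy number, and correlates coverage tracks with
    genome features such as replication timing and SINE density. Includes
    a simulator of DNA-isolation retrieval bias in which fragment recovery
    depends on GC content, chromatin compaction, and lysis duration, so
    that every pipeline stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    methods,
    S4Vectors,
    data.table,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
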