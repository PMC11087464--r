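Package: lrtsim
Title: Simulation and Benchmarking of Long-Read RNA-Seq Isoform Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-level simulator for long-read RNA sequencing of spliced
    transcriptomes and a matching evaluator for isoform-detection results.
    The simulator generates novel alternative-splicing isoforms (exon
    skipping, intron retention, alternative donor/acceptor sites) up to a
    target transcriptome complexity, assigns per-isoform sequencing depths
    with a range-restricted log-normal mixture at the gene level and a
    mean-preserving Zipf rank model at the isoform level, transcribes
    stranded cDNA from a reference genome, and emits error-containing,
    optionally 5'/3'-truncated reads as provenance-tagged FASTQ. The
    evaluator compares isoform-set GTFs by exact splice-boundary matching
    (precision/sensitivity), classifies query isoforms as FSM, ISM, NIC,
    NNC or intergenic, and computes base-pair Jaccard similarity. A fixture
    generator produces toy genomes and annotations so the whole pipeline
    runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    IRanges,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
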