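Package: pseudotx
Title: Classification and Analysis of Processed Pseudogene Transcripts from
    Long-Read Isoform Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify and characterise processed pseudogene
    transcripts among full-length (long-read) transcript models. Transcript
    models are compared against a reference gene annotation and a retrocopy
    track to call pseudogene transcripts, decide whether they are independent
    of known genes, and orient them relative to the parent gene. Per-transcript
    evidence features include canonical polyadenylation-motif scanning near the
    3' terminus and CAGE peak support at transcription start sites. An ORF
    toolkit measures coding potential, the fraction of the parental ORF left
    intact, and codons contributed by pseudogenes to gene-pseudogene fusion
    transcripts. Selection on pseudogene ORFs is estimated with a
    Nei-Gojobori (1986) pairwise dN/dS estimator over codon alignments threaded
    from global protein alignments. A synthetic genome and retrotransposition
    simulator with a machine-readable truth manifest makes every stage testable
    without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
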