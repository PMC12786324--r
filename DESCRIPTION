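Package: circamotif
Title: Circadian Cis-Regulatory Motif Scanning of TSS-Anchored Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts transcription start site (TSS)-anchored promoter windows
    from genomic FASTA, scans them for circadian cis-regulatory elements with
    two complementary strategies (position weight matrix scoring with min-max
    relative-score thresholding, and exact/degenerate IUPAC consensus matching
    for the E-box, D-box, CRE, Pdp1 and PER-repeat families), and tests motif
    enrichment against zero- or first-order Markov background resampling with
    empirical p-values and multiple-testing correction. Includes a synthetic
    promoter generator that plants motif cores at known TSS-relative positions
    and emits a truth table, so every pipeline stage is testable without
    genome downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
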