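Package: cubtools
Title: Codon Usage Bias Analysis for Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of codon usage bias in bacterial coding
    sequences: codon counting under genetic code table 11, composition and
    bias indices (GC1/GC2/GC3/GC3s, RSCU, CAI, CBI, FOP, ENC, GRAVY,
    aromaticity), mutation-versus-selection diagnostics (neutrality plot,
    Wright's expected ENC curve, PR2-bias plot), correspondence analysis of
    RSCU profiles, optimal-codon identification from CAI-defined expression
    extremes, codon-pair context analysis with adjusted residuals, and
    genome clustering on RSCU and context profiles. Includes a
    mutation-selection synthetic genome generator with recorded truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
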