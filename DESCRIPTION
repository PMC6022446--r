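Package: virobias
Title: Quantifying Amplification and Enrichment Bias in Virome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify the compositional and coverage biases that
    virus enrichment and random whole-genome amplification (multiple
    displacement amplification and sequence-independent single-primer
    amplification) introduce into shotgun viromes. Provides absolute qPCR
    quantification against standard curves and mock-community composition
    tracking, strict-identity read mapping and RPKM contig abundance with
    fold-change bias profiling, per-base coverage evenness statistics
    (trimmed coefficient of variation, Lorenz curves and Gini, profile
    correlations, high-coverage peak detection), sequence-signal analyses
    (Trifonov linguistic complexity, primer-site scanning, primer trimming
    and primer-dimer tracks, junction-read circularity detection), and
    community-level dissimilarity and NMDS ordination, together with a
    synthetic mock-community read simulator that injects the characterised
    bias modes so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    vegan,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
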