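Package: plexquant
Title: Isobaric 8-Plex Proteomics Quantification with PTM-Level
    Deregulation Calling and qPCR Array Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for isobaric-tag (iTRAQ 8-plex) reporter
    quantification of brain-region proteomics experiments: peptide-spectrum
    match confidence filtering on search-engine scores, log2 transformation,
    per-channel median normalization, per-replicate mean-centering, rollup of
    modified peptides and proteins, transgenic-versus-wild-type ratio
    computation with relative-standard-deviation and fold-change deregulation
    calling, normalization of phosphopeptide and deglycopeptide ratios against
    protein expression, N-glycosylation sequon validation, principal-component
    sample quality control, a 2^-ddCt quantitative PCR array module with
    median-of-targets normalization, cross-region overlap (Venn) counting and
    protein-class summaries, and a ground-truth-labelled synthetic data
    generator for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
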