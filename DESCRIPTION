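Package: ptmquant
Title: Protein Abundance and PTM Stoichiometry from Peptide-Level Mass
    Spectrometry
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of bottom-up proteomics data at the
    peptide level. Classifies quantified peptide chemoforms by
    modification status (Q/M/NM), corrects common sources of technical
    variation against spike-in isotopologue standards (equimolar
    isotopologue, ratio-to-isotopologue, total ion current and internal
    reference normalization), and computes relative protein abundance and
    per-site post-translational modification stoichiometry -- exactly
    when chemoform coverage is complete, approximately (by inference from
    detected chemoforms, without imputation) when it is not. Includes a
    simulator of peptide-level quantitative experiments with ground-truth
    molarities, spike-in standards and injected technical artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
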