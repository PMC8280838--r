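Package: phosphotriage
Title: Kinase-Substrate Triage from SILAC and TMT Phosphoproteomics Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for triaging candidate kinase substrates from paired
    quantitative phosphoproteomics screens, built around the ULK1/2
    autophagy kinases. Implements SILAC forward/reverse depletion calling
    with WT/WT label-bias exclusion and protein-level-change flagging, a
    consensus-motif grammar and matcher with positional enrichment (logo)
    matrices, TMT 10-plex starvation time-course normalisation, contrast
    and reference-profile triage with correlation clustering,
    cross-referencing of the two screens into a high-confidence shortlist
    with conservation and interaction-network annotation, peptide-array
    variant design, and a synthetic-screen generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
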