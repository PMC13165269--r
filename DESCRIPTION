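Package: glycoquench
Title: Fluorescence-Quenching Binding Analysis and Protein Antiglycation Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of small-molecule binding to serum albumin by
    steady-state fluorescence quenching (Stern-Volmer and double-logarithmic
    fits, quenching-mode classification, van't Hoff thermodynamics, binding-force
    typology, competitive site-marker displacement) together with quantification
    of protein glycation markers (fructosamine, protein carbonyls, free lysine
    modification, fluorescent advanced glycation end-products), dose-response
    IC50 estimation, and circular-dichroism estimation of alpha-helix content
    from mean residue ellipticity. Includes a seeded synthetic-data generator
    emulating static-quenching titrations, glycation assay panels and Hill-shaped
    dose-response curves, so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
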