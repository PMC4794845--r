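Package: dpmquant
Title: Quantitation of Degenerative Protein Modifications and Protein
    Regulation from iTRAQ Peptide-Spectrum-Match Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for isobaric-tag (iTRAQ) shotgun proteomics
    of pooled case/control brain tissue. Reads peptide-spectrum-match (PSM)
    tables, applies target-decoy qualification filtering (doubling-formula
    FDR, unused protein score, peptide confidence), infers protein-level
    relative abundance with weighted log-ratio statistics (error factor,
    Student t), area-based G-tests with Benjamini-Hochberg correction and
    %CV-based regulation calls, quantifies deamidation and citrullination
    stoichiometry and per-site group differences, scores protein
    degradation byproducts via cross-species alignment and semi-tryptic
    terminal rules, and ships a seeded synthetic PSM generator for
    end-to-end validation against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
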