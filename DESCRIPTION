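Package: citscape
Title: Site-Specific Citrullinome Analysis from MaxQuant-Style Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for proteome-wide citrullination analysis:
    discrimination of the citrullination mass increment from deamidation and
    natural isotope substitutions, localization-probability filtering of
    MaxQuant-style evidence tables into a quantified site matrix,
    modification stoichiometry (occupancy), PADI4-inhibitor dose-response and
    IC50 fitting, enrichment of citrullination in structural and sequence
    contexts (disordered regions, domains, nuclear localization signals,
    coordination number, relative solvent accessibility, pLDDT, secondary
    structure), PTM crosstalk and iceLogo-style motif enrichment,
    transcription-factor target scoring, and peptide-microarray
    autoantibody-reactivity analysis. A synthetic-data generator with a
    ground-truth ledger emulates every input so the whole pipeline is
    testable without the deposited raw data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    Biostrings
Suggests: testthat (>= 3.0.0), withr, rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
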