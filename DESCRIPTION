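Package: aademand
Title: Factorial Modelling of the Minimum Metabolic Demand for Amino Acids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a factorial model of the minimum metabolic demand (MMD)
    for total protein and each amino acid in the healthy young adult male.
    Obligatory losses (protein-turnover-associated oxidation, gut endogenous
    losses, urinary free amino acids and peptides, hair/skin/nail and
    miscellaneous losses, and other losses from irreversible modification and
    functional conversion) are assembled per amino acid and the inevitable
    first-pass oxidation of absorbed amino acids is resolved as a fixed point,
    giving per-amino-acid and aggregate demands with propagated uncertainty.
    Includes one-at-a-time sensitivity analysis of each loss parameter,
    construction of protein-quality scoring patterns, DIAAS-style scoring of
    dietary protein sources with limiting-amino-acid identification and
    back-calculation of the protein intake required to meet the demand, plus
    derivation utilities for the minor loss components from nitrogen totals,
    composition tables and urinary metabolite excretion records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
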