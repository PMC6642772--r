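Package: oxcap
Title: Oxidative Capacity and Redox Thermodynamics of Nitrification and
    Sulfur-Based Autotrophic Denitrification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting the accumulation of intermediate compounds
    (nitrous oxide, nitrite, elemental sulfur) in nitrification and
    sulfur-driven autotrophic denitrification reactors from bulk-liquid
    chemistry. Computes Gibbs free energy of candidate redox reactions with
    concentration-dependent reaction quotients, normalized per mole of
    electrons transferred; pH- and temperature-dependent half-reaction
    potentials assembled into redox ladders; and the oxidative capacity (OXC)
    of the bulk liquid in electron equivalents per liter. Ships a bench-scale
    reactor data set and an ordinary least-squares modelling interface
    (oxc_lm) relating OXC to specific intermediate production rates, with
    confidence and prediction bands, plus a seeded synthetic stage generator
    for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
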