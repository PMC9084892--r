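Package: foldbind
Title: Protein Stability and Ligand-Binding Analysis for the VWF A1 Domain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of the conformational stability and
    GPIb-alpha-binding energetics of the von Willebrand factor A1 domain
    and its O-glycosylated linker constructs. Implements global
    three-state (native/intermediate/denatured) linear-extrapolation
    fits to urea denaturation curves read out by the tryptophan
    fluorescence intensity ratio I350/I330, derivative-based melting
    temperature and aggregation-onset detection from thermal ramps,
    global one-site kinetic fits to biolayer interferometry sensorgrams
    with double referencing, one-site isothermal titration calorimetry
    isotherm fits with free-energy decomposition, and peptide-level
    hydrogen-deuterium exchange difference maps. Seeded synthetic-data
    generators emulate all five measurement modalities so every
    analysis stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
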