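Package: thermonet
Title: Thermodynamics-Based Analysis of Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for thermodynamic analysis of metabolic networks:
    Legendre-transformed standard Gibbs energies of formation at
    physiological pH and ionic strength, pseudoisomer (protonation-state)
    grouping of biochemical reactants, group-contribution estimation of
    formation energies, Gibbs energies of transmembrane transport
    reactions, network-embedded thermodynamic (NET) analysis by linear
    programming in log-concentration space (feasibility checking,
    reaction Gibbs-energy ranges, concentration-range tightening,
    directionality assignment, regulatory-site flagging), and the
    non-equilibrium flow-force relation for single enzymatic reactions.
    Includes a yeast glycolysis reference dataset and a seeded toy-network
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    boot,
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
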