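Package: kinquench
Title: Enzyme Inhibition Kinetics, Fluorescence Quenching and Binding
    Thermodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Characterization of reversible enzyme inhibitors from
    plate-reader progress curves and fluorescence titrations: initial
    rates, four-parameter logistic IC50 fits, Michaelis-Menten and
    Lineweaver-Burk analysis with secondary replots and a global
    mixed-model fit for Ki and Ki', inhibition mechanism classification,
    reversibility assessment, first-order inactivation kinetics with
    transition free energies, Stern-Volmer and double-logarithmic
    fluorescence quenching analysis, Van 't Hoff thermodynamics with
    binding-force classification, synchronous-fluorescence peak-shift
    detection, and Forster resonance energy transfer distance
    estimation.  Seeded simulators generate every input the analyses
    consume, with known ground truth, so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
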