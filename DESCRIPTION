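Package: blmpore
Title: Water-Pore Analysis of Planar Lipid Bilayer Ramp Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for electroporation experiments on planar
    lipid bilayers exposed to linearly rising transmembrane voltage or
    current. Detects the breakdown event in raw electrical traces, estimates
    membrane resistance from the RC response to a current ramp, extracts the
    rate of capacitance change at rupture, fits the two-parameter
    strength-duration (rheobase/chronaxie) curve, infers the water-pore
    radius and spontaneous pore-formation rate from the exponential voltage
    dependence of the capacitance-change rate, and converts capacitance
    excess into the fraction of membrane area occupied by water pores via a
    two-phase dielectric model. Includes a synthetic ramp-experiment
    simulator with ground truth for end-to-end validation, and bundled
    reference measurement tables for POPC, POPS and POPC:POPS (1:1)
    bilayers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    minpack.lm
Config/testthat/edition: 3
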