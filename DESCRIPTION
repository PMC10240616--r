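Package: macpol
Title: Continuous Fuzzy-Logic Modelling of Macrophage Polarization Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Transforms Boolean transcriptional regulatory networks into
    continuous ordinary differential equation systems with a fuzzy-logic
    (probabilistic AND/OR/NOT) composition and a sigmoid characteristic
    function, integrates them to steady state under clamped extracellular
    inputs, and labels the resulting states as macrophage polarization
    phenotypes (M0, M1, M1a, M2a-M2d and their hybrids). Ships a vendored
    29-node macrophage network, dose-scan, microenvironment, constant
    perturbation and two-dimensional phenotype-map experiments with
    transition-threshold detection, plus a random Boolean network generator
    and an exhaustive synchronous attractor oracle for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
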