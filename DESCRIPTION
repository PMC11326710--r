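Package: photofba
Title: Flux Balance Analysis of Light-Limited Phototrophic Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based modelling of light-limited phototrophic growth.
    Extends flux balance analysis with a saturating quantum-yield model of
    photon uptake, a light-proportional ATP demand for photodamage repair,
    ratio-coupled physiological constraints, and light-dependent biomass
    objective functions. Includes an SBML Level 3 (fbc) reader and writer, a
    bounded-variable simplex solver with parsimonious flux selection and flux
    variability analysis, weighted nonlinear least-squares estimation of the
    light parameters against growth-irradiance data, normalized sensitivity
    analysis, and an analytically solvable toy phototroph network for
    validation and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
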