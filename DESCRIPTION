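Package: galvanic
Title: Galvani Offset Potentials in Periodic Constant-pH Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Diagnoses and corrects the Galvani offset potential that arises in
    periodic-boundary simulations treated with tinfoil Ewald electrostatics.
    Computes smoothed and exact Ewald potential maps of periodic point-charge
    systems on regular grids, classifies grid cells by molecular species from
    Gaussian occupancy maps, estimates the bulk-water Galvani potential from the
    dominant solvent peak and its dependence on the water volume fraction, runs
    a toy-scale nonequilibrium Monte Carlo constant-pH engine with the offset
    work correction, and combines runs across pH and Galvani-potential
    conditions with binless WHAM to produce titration curves and fitted pKa
    values. Includes seeded synthetic generators (neutral electrolytes,
    membrane-mimicking charged slabs with closed-form interfacial potentials,
    Bernoulli protonation series) with exact ground truth, plus PQR and OpenDX
    readers and writers and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
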