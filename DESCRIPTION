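Package: rosewater
Title: Monte Carlo Simulation and Anomaly Mapping for the Two-Dimensional
    Rose Model of Water
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Canonical-ensemble (NVT) Metropolis Monte Carlo for the rose
    model of water: two-dimensional Lennard-Jones disks carrying an
    orientation-dependent hydrogen-bonding potential built from a three-petal
    rose function. Provides the pair potential and its radial virial, a
    cell-list accelerated sampling engine with mean-square-displacement
    tracking, the waterlike observable suite (virial pressure, radial
    distribution function, translational order parameter, three- and six-fold
    bond-orientational order, two-body excess entropy, hydrogen-bond counts,
    pseudo-diffusion coefficient), and tools that scan density-temperature
    grids to locate the density, diffusion, structural, orientational and
    entropy anomaly regions and report their hierarchy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
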