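Package: hgdpd
Title: Dissipative Particle Dynamics Modelling of Homogalacturonan in Water
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A dissipative particle dynamics (DPD) simulation engine and
    parametrization toolkit for coarse-grained modelling of homogalacturonan
    (pectic polysaccharide) chains in water. Provides the standard DPD pair
    forces with a generalized dissipative weight exponent, harmonic distance
    and angular bonds, cell-list neighbour search and a modified velocity
    Verlet integrator; a step-wise iterative nearest-neighbour clustering
    algorithm that maps fine-grained molecular trajectories onto
    equal-occupancy coarse-grained beads; trajectory observables (radial
    distribution functions, mean-squared displacement and diffusion
    coefficients, velocity statistics, bonded-geometry distributions); and a
    calibration workflow that fixes the DPD time scale by velocity or
    diffusion matching and fits repulsion and bonded parameters against
    reference data. Includes synthetic-trajectory generators for testing the
    full pipeline and readers/writers for extended XYZ and GRO formats.
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
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
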