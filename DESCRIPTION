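Package: symbem
Title: Symmetric Boundary Element Forward Solver for EEG, MEG, EIT and
    Intracranial Potentials
Version: 0.1.0
Authors@R:
    person("symbem", "developers", email = "symbem@example.org",
           role = c("aut", "cre"))
Description: Forward field computation for quasistatic bioelectromagnetics on
    nested head models with piecewise constant conductivity. Implements the
    symmetric Galerkin boundary element method with analytic singular triangle
    integrals and adaptive quadrature, and produces lead fields for scalp
    potentials (EEG), magnetic sensors (MEG), scalp current injection (EIT)
    and internal potentials. Includes multilayer concentric-sphere analytical
    solutions (Legendre series and the Sarvas formula), RDM/MAG validation
    metrics, sphere mesh generators, and readers/writers for .tri mesh,
    geometry, conductivity, sensor and ASCII matrix formats with an
    assemble/minverser/gain command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
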