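Package: permeakit
Title: Single-Channel Permeability from Trajectory Data by Three Independent Routes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the single-channel permeability of an ion or small solute
    from one-dimensional collective-variable trajectory data by three
    independent routes: the inhomogeneous solubility-diffusion equation
    (potential of mean force plus position-dependent diffusion coefficient),
    Markovian milestoning mean-first-passage times on Voronoi-tessellated
    cells, and steady-state flux under an applied field with
    Goldman-Hodgkin-Katz conversion of conductance to permeability. Includes
    a WHAM-style umbrella-sampling reweighting estimator, an
    autocorrelation-based diffusion-profile estimator, and an overdamped
    Langevin (Brownian dynamics) simulator that generates ground-truth
    trajectories so every estimator is testable without molecular-dynamics
    software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
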