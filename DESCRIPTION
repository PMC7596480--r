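Package: eustasim
Title: Brownian Dynamics of Nanoparticle Transport Through the Eustachian Tube
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates intratympanically injected nanoparticles travelling from
    the middle ear to the contralateral ear through a two-tube-plus-cavity model
    of the Eustachian tube and nasopharynx. Particles follow overdamped Langevin
    (Brownian) dynamics with Stokes-Einstein diffusion and optional Cunningham
    slip correction, a constant axial external force, and softened pairwise
    Coulomb repulsion between charged particles; reflecting walls confine the
    ensemble and an absorbing plane at the contralateral tube end records
    arrivals. Includes an independent one-dimensional drift-diffusion
    (Crank-Nicolson and eigenfunction-series) first-passage oracle for
    validation, scenario sweeps over particle size, surface charge and force
    direction with replicate statistics, and monotone bisection calibration of
    the model's free scalars.
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
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
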