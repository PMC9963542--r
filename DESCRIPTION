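Package: acoustoLBM
Title: Immersed-Boundary Lattice Boltzmann Simulation of Acoustophoretic
    Microparticle Focusing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-dimensional immersed-boundary lattice Boltzmann (IB-LBM)
    simulator for the manipulation of microparticles in microchannels under
    standing surface acoustic waves (SSAW). Implements a D2Q9 BGK solver with
    Shan-Chen velocity-shift forcing, link bounce-back and Zou-He style wall
    reconstruction, hat-kernel immersed-boundary coupling of a Lagrangian
    membrane particle, the primary acoustic radiation force with its acoustic
    contrast factor, and a physical-to-lattice unit mapping. Ships the
    classical validation scenarios (Poiseuille flow, lid-driven cavity at
    Re = 100 against the Ghia et al. profile, low-Reynolds cylinder drag) and
    SSAW particle-focusing experiments with parametric sweeps over initial
    position, particle radius and particle material.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
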