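Package: menpsim
Title: Magnetoelectric Nanoparticle Simulation for Neural Magnetic Particle Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale forward models for core-shell magnetoelectric
    nanoparticles (cobalt ferrite core, barium titanate shell) as reporters of
    neuronal extracellular electric fields in magnetic particle imaging (MPI).
    Provides lumped (zero-dimensional) particle physics coupling Langevin
    superparamagnetism, magnetostriction and piezoelectric stress; MPI harmonic
    spectroscopy of the nonlinear magnetization under an oscillating drive
    field; a linear magnetoelectric mapping from extracellular electric fields
    to magnetization changes; volume-conductor forward modelling of
    extracellular potentials around compartmental neuron morphologies (SWC);
    a layered cortical spiking-network voxel model; and Monte Carlo
    advection-diffusion sampling of perfusing particles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
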