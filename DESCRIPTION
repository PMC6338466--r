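Package: mtstream
Title: Coarse-Grained Simulation and Timescale Analysis of Motor-Driven
    Microtubule Streaming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Langevin-dynamics simulation of two-dimensional semiflexible
    microtubule filaments driven by polarity-selective effective molecular
    motors, together with the analysis stack that decomposes cytoskeletal
    streaming into five characteristic timescales: antialigned sliding,
    polarity inversion, maximal activity, collective migration, and active
    rotation.  Provides bead-spring filament mechanics (harmonic bonds,
    cosine bending, WCA excluded volume), a transient harmonic effective-motor
    interaction between antialigned filament pairs, a velocity-Verlet Langevin
    integrator with cell-list neighbour search, mean-squared-displacement and
    displacement-correlation estimators, local polar order and its relaxation,
    orientational correlation fits, chronology assembly, FRAP-style labelling,
    and a LAMMPS-style text dump reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
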