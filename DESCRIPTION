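Package: hpfmd
Title: Hybrid Particle-Field Molecular Dynamics of Surfactant Self-Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained hybrid particle-field molecular dynamics
    (hPF-MD) for amphiphile self-assembly in explicit coarse-grained
    solvent, with the complete analysis pipeline for micellization
    studies.  Particles evolve under density-functional field forces
    computed on a mesh (cloud-in-cell assignment, Flory-Huggins-like
    interaction matrix, compressibility penalty), harmonic bonded
    forces, optional mesh electrostatics, velocity-Verlet integration
    and an Andersen thermostat.  Analysis covers cluster-size
    distributions and free-monomer fractions, radial distribution
    functions, mean-square displacement and Einstein diffusion fits,
    critical micelle concentration by two-regime linear fitting,
    Ornstein-Zernike small-angle scattering line shapes, and the
    surfactant packing parameter.  Configurations are read and written
    in GRO and multi-frame XYZ formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
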