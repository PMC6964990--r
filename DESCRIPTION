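Package: hrdme
Type: Package
Title: Hierarchical Reaction-Diffusion Master Equation Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Event-driven stochastic simulation of reaction-diffusion
    kinetics on a hierarchy of nested Cartesian meshes. Molecules are
    tracked individually with the next-particle method; bimolecular
    reactions use mesoscopic rates derived from microscopic
    (Collins-Kimball-Smoluchowski) rate constants via a lattice Green's
    function correction, dissociation products are resolved on a fine
    mesh to capture fast rebinding, and molecules migrate to coarser
    meshes as they diffuse, giving fine-mesh accuracy at near
    coarse-mesh cost. Includes a well-mixed direct-method SSA and a
    single-mesh solver mode as reference oracles, built-in benchmark
    models, ensemble/rebinding-time observables, and a command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
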