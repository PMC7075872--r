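Package: linkerelast
Title: Elastic Properties of the Kinesin Neck Linker from Network Modes and
    Pulling Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for the mechanics of the kinesin neck-linker
    peptide. Performs approximate normal-mode analysis of a C-alpha elastic
    network with exponentially attenuated pair force constants, computes
    per-residue deformation energies and a rigid-body-similarity dynamic
    domain decomposition of a motor structure. A coarse-grained overdamped
    Langevin bead-spring simulator generates ensembles of constant-force
    stretching and force-off relaxation trajectories of short peptides
    (wild-type linker, alanine-substitution mutants and a poly-alanine
    reference). Work samples from the ensembles feed fluctuation-relation
    free-energy estimators: the Jarzynski exponential average, the Gaussian
    closed form, and the crossing point of forward/reverse work
    distributions, with bootstrap uncertainties, plus worm-like-chain
    force-extension and fractional-extension stiffness fits.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    igraph,
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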