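Package: clamshellfe
Title: Free-Energy Landscapes of Clamshell Ligand-Binding Domains
Version: 0.1.0
Authors@R:
    person("clamshellfe", "developers", email = "clamshellfe@example.org",
           role = c("aut", "cre"))
Description: Tools for reconstructing ligand-binding free energies of
    bilobal ("clamshell") receptor ligand-binding domains from biased
    sampling data. Provides PDB and trajectory input/output, Kabsch
    superposition, RMSD/RMSF analysis, reaction-coordinate evaluators
    (center-of-mass distances, interdomain angle and torsion), rigid-body
    principal component analysis of two-domain motion, an overdamped
    Langevin simulator on analytic potentials with umbrella and
    metadynamics biasing, a WHAM estimator with histogram-overlap and
    batch-convergence diagnostics, Gaussian-hill metadynamics free-energy
    reconstruction, three-state assignment by reference RMSD, and a
    two-substep combination of opening and dissociation free energies
    into total binding free energies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
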