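Package: amdtools
Title: Accelerated Molecular Dynamics Boost, Reweighting, and Contact-Based
    PCA Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis machinery for accelerated molecular dynamics (aMD)
    studies of protein-RNA recognition dynamics, exemplified by the YTH
    reader domain bound to N6-methyladenosine RNA. Implements the aMD boost
    potential with dual-boost parameter estimation from conventional-MD
    energy averages, exponential and Maclaurin-series reweighting to
    free-energy surfaces with basin and barrier readout, a Langevin toy-model
    simulator for validating the boost/reweight cycle, Cartesian principal
    component analysis of trajectories with cross-projection onto an
    essential subspace, native-contact determination with per-frame minimum
    heavy-atom distances, contact-based PCA with component ranking, and a
    synthetic two-state recognition-loop trajectory generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
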