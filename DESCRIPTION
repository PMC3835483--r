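Package: icpca
Title: Internal-Coordinate Principal Component Analysis of Conformational
    Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies the thermodynamically most relevant internal degrees
    of freedom of a small molecule from a conformational ensemble. Enumerates
    bonds, bond angles and proper dihedrals on the molecular graph, measures
    them frame by frame, performs covariance PCA per coordinate kind, and
    ranks features by an eigenvalue-weighted loading score over the principal
    components that recover 90 percent of the variance, isolating the top
    10 percent. Companion analyses: mass-weighted Kabsch superposition with
    mean and representative structure selection, per-frame energy-term
    summaries, and a simplified two-dielectric (polar head group versus
    hydrophobic membrane core) screened-Coulomb electrostatic potential map
    on a molecular dot surface. Includes seeded synthetic-data generators
    emulating force-field ensembles so the full pipeline is testable without
    molecular dynamics trajectories.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
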