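Package: dopaphore
Title: Pharmacophore Screening for Dopamine D2 Full Agonists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A 3D ligand-based virtual screening toolkit built around a
    refined dopamine D2 receptor full-agonist pharmacophore. Provides a
    curated 30-ligand training library (full agonists, partial agonists and
    structurally similar inactives), a deterministic systematic torsion
    search conformer generator with MMFF94 strain ranking, perception of
    ligand annotation points (protonated amine cation, aromatic ring with
    normal, in-plane hydrogen-bond projections), a rigid-superposition
    feature matcher with excluded-volume and excluded-oxygen steric
    screening, receptor-anchor hydrogen-bond geometry evaluation, and a
    seeded calibration search that tunes the placement of the feature
    cluster against the excluded-volume shell by training-set hit-rate
    discrimination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineR,
    testthat (>= 3.0.0)
SystemRequirements: Open Babel (obabel and obenergy on the PATH)
Config/testthat/edition: 3
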