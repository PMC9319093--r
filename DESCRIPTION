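Package: gpcrstars
Title: Star-Based Quality Ranking and Activation-State Geometry for GPCR
    Structural Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for ranking G-protein-coupled receptor (GPCR) structural
    models produced by homology modelling, threading, or deep-learning
    predictors. Implements a quartile-binned "Stars" aggregation of twelve
    protein global-quality metrics, a secondary three-criterion (V1-V3)
    ranking combining star totals, ionic-lock geometry, and virtual-screening
    enrichment AUC, Ballesteros-Weinstein generic residue numbering from
    per-segment anchors, activation-state geometry metrics (ionic lock,
    aspartate cage, TM3-TM6 cytoplasmic distance), per-frame trajectory
    analysis with RMSD series and interaction fingerprints, binding-pocket
    residue fingerprint matrices, and synthetic-data generators (ideal 7-TM
    bundles, noisy trajectories, two-class docking score tables) so every
    stage can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
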