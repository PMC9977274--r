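Package: roamnet
Title: Roaming Entropy Trajectories and Brain Structural Covariance Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the mouse individuality paradigm: Shannon
    roaming entropy from RFID antenna-contact logs, trajectory stratification
    of enriched-housed mice into sustained ("flat") and habituating ("down")
    roamers, Bayesian variance-component repeatability of standardized
    entropy, atlas region-of-interest volumetry statistics (Welch tests,
    false discovery rate, standardized mean differences), structural
    covariance network construction and correlation-matrix equality tests,
    and network-based statistics with permutation family-wise error control.
    Includes seeded generators for synthetic tracking logs and volume tables
    with planted ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    cluster,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
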