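Package: neuroenrich
Title: Enrichment Analysis for Neuroimaging Position and Connection Sets
Version: 1.0.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical enrichment analysis for large-scale neuroimaging
    results. Tests whether a set of neural positions (voxels or parcels), or a
    set of neural connections (position pairs), over-represents known brain
    annotation classes such as functional networks or anatomic structures.
    Provides the hypergeometric over-representation test for position and
    connection groups, a non-parametric degree-preserving permutation (DPP)
    test for connection groups based on double-edge-swap graph randomization,
    Benjamini-Hochberg and Bonferroni multiple-testing correction, frequency
    ratio effect sizes, readers for NIFTI-1 volumes and tabular position,
    pair, background and annotation files, BrainNet Viewer export, a
    simulation harness with power-law random graphs and implanted noisy
    bicliques for calibration and power studies, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
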