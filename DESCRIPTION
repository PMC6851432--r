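Package: tbmtools
Title: Torsion-Space Quality Assessment and Molecular-Replacement
    Preparation for Template-Based Protein Models
Version: 0.1.0
Authors@R:
    person("TBM", "Assessors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Toolkit for assessing predicted protein structures against
    experimental targets in the style of CASP template-based-modeling
    evaluations.  Computes backbone (phi, psi, omega) and sidechain
    (chi1, chi2) dihedral agreement scores with burial weighting, flags
    implausible peptide bonds (cis/trans flips and twists), ranks
    predictor groups by adjusted z-scores over external metric tables
    (GDT_HA, lDDT, CADaa, SG, ASE), prepares models for molecular
    replacement by inflating B-factors from coordinate-error estimates
    and applying quality filters, and triages experimental templates by
    resolution and MolProbity score.  Includes an ideal-geometry peptide
    builder for fully synthetic, ground-truth-known test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
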