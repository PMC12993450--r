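Package: ventmark
Title: Ventricular and Choroid Plexus Biomarkers from Synthetic Brain Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline linking cerebrospinal-fluid
    system markers to cortical protein aggregation. Generates synthetic
    cohorts from a linear-Gaussian structural-equation model together with
    3D brain phantoms (label volumes plus amyloid- and tau-PET SUVR
    volumes), extracts image-derived biomarkers (ventricular and choroid
    plexus volumes, Evans' Index, composite and ventricular SUVRs), stages
    participants by amyloid/tau positivity, and provides the downstream
    statistics: reference Z-scores, ANOVA with Tukey HSD and
    Benjamini-Hochberg correction, Spearman correlations, standardized
    multivariable regression, voxel-wise t-maps with random-field-theory
    correction, and sequential mediation analysis with bias-corrected
    bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
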