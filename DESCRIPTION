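Package: longpet
Title: Longitudinal FDG-PET Quantification with Partial Volume Correction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for longitudinal brain FDG-PET quantification and group
    inference. Implements iterative reblurred Van Cittert deconvolution for
    partial volume correction, cerebellum-referenced SUVR imaging and
    region-of-interest summaries, per-region linear mixed-effects modelling of
    carrier-by-time interactions, voxelwise paired-t analysis with cluster-level
    family-wise error control by sign-flip permutation, and cohort conversion
    statistics (chi-square, Kaplan-Meier, Fleming-Harrington weighted log-rank).
    A seeded synthetic phantom cohort generator emulates the statistical
    structure of a two-group longitudinal PET study so every stage can be
    exercised and calibrated without access to restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    lme4,
    survival,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'cli.R'
    'cohortstats.R'
    'interface.R'
    'longmodel.R'
    'phantom.R'
    'pvc.R'
    'roistats.R'
    'voxelstats.R'
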