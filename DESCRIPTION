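Package: adaptdecay
Title: Decay of fMRI Adaptation: Block GLM, Exponential Time-Constant
    Fitting, and Nonparametric Group Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating the time constant of blood
    oxygenation level dependent (BOLD) adaptation from block-design
    fMRI experiments in which trial onset asynchrony (TOA) is varied
    across blocks.  Provides a seeded synthetic-cohort generator with
    known ground truth, temporal high-pass filtering and spatial
    smoothing, two-gamma hemodynamic response modelling and per-voxel
    general linear model estimation, least-squares fitting of the
    exponential decay model beta(TOA) = a + b*exp(-TOA/tau) by variable
    projection, voxelwise and region-of-interest Mann-Whitney group
    comparison with rank-based effect sizes, and Monte-Carlo
    cluster-extent correction for whole-brain maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
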