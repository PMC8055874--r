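Package: gliomaRx
Title: Image-Driven Reaction-Diffusion Modelling of High-Grade Glioma
    Response to Chemoradiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forecasts the spatial response of high-grade gliomas to
    chemoradiation from longitudinal MRI-derived cellularity maps. Implements
    a family of mechanically-coupled single- and two-species reaction-diffusion
    tumor growth models with spatially varying radiotherapy and chemotherapy
    efficacy, per-patient parameter calibration by bounded Levenberg-Marquardt,
    AIC-based model selection across the 40-member model family, and global
    (volume error, Dice) plus voxel-level (Pearson, Lin's concordance, Kendall)
    error analysis. Includes a digital-phantom generator that synthesizes
    longitudinal virtual-patient datasets (ADC, pre/post-contrast T1, tumor
    masks, tissue labels) so that calibration, selection, and evaluation are
    fully testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
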