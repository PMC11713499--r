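Package: sctQA
Title: Quality Assurance Toolkit for Synthetic CT in MR-Only Radiotherapy Planning
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validation pipeline for MR-derived synthetic CT against a planning
    CT: body-masked preprocessing and grid resampling, Hounsfield-unit image
    quality metrics (ME, MAE, RMSE, PSNR, SSIM), cumulative dose-volume
    histogram metrics (V_x%, D-mean, D-max) with reference/evaluated
    differencing, 3D gamma analysis (dose-difference / distance-to-agreement)
    with a brute-force verification oracle, and the statistical battery linking
    image quality to dosimetric agreement (Shapiro-Wilk, t-test, Wilcoxon
    signed-rank, Spearman, Bonferroni). A deterministic digital head-phantom
    generator with a parametric conversion-error model and a toy exponential
    depth-attenuation dose engine provides fully synthetic paired cases so the
    whole pipeline is testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
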