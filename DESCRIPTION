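Package: fibrostage
Title: Staging Liver Fibrosis with Multi-Model Diffusion-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative diffusion-weighted MRI analysis pipeline for
    liver fibrosis staging. Provides closed-form forward models and
    voxel-wise Levenberg-Marquardt fitting for the monoexponential (ADC),
    diffusion-kurtosis (D_app, K_app) and stretched-exponential (DDC,
    alpha) signal representations; a synthetic phantom generator that
    simulates METAVIR-staged cohorts with stage-conditional diffusion
    parameters under Rician noise; region-of-interest summarization of
    parametric maps; and the staging statistics (one-way ANOVA with LSD
    post hoc tests, Spearman and Pearson correlations with Fisher-z
    confidence intervals, and ROC analysis with Youden-index cutoffs and
    DeLong confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
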