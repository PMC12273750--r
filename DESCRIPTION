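Package: sepsishsi
Title: Sepsis Diagnosis and Mortality Prediction from Skin Hyperspectral Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for sepsis diagnosis and 30-day mortality
    prediction from hyperspectral imaging (HSI) of ICU patients' skin.
    Provides a seeded synthetic cohort generator (chromophore-based skin
    reflectance spectra, circular skin annotations, RGB renderings, clinical
    tables with planted informative features), the deterministic
    preprocessing chain (white/dark reference calibration, per-pixel l1
    spectral normalization, annotation cropping, bilinear rescaling, site
    stacking, -1 imputation), band-ratio tissue parameter indices (oxygen
    saturation, perfusion, hemoglobin, water), convolutional and multimodal
    fusion classifiers trained with AdamW, exponential learning-rate decay
    and stochastic weight averaging, a balanced random-forest clinical
    model, and an evaluation harness with nested cross-validation,
    logit ensembling, bootstrap AUROC confidence intervals, recursive
    feature elimination, and Welch/Bonferroni group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ranger,
    EBImage,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
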