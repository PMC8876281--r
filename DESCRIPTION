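Package: pcscale
Title: Quantitative Prognostic Scoring for Posterior Circulation Stroke from Noncontrast CT Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantitative prognosis scoring of posterior
    circulation ischemic stroke from labeled noncontrast CT volumes.
    Computes structure volumes and the ten lesion-proportion parameters
    from paired structure-label volumes and binary ischemic lesion masks,
    derives the automated posterior circulation Acute Stroke Prognosis
    Early CT Score (pc-ASPECTS) and a cross-validated quantitative
    integrated score, and evaluates predictors with ROC/AUC, operating
    points and the DeLong paired test. Includes a synthetic head-phantom
    and cohort generator with a stated logistic outcome model, and a
    desk-scale encoder-decoder segmentation trainer, so every stage of
    the pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    png
Config/testthat/edition: 3
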