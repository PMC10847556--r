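Package: pcgscreen
Title: Heart-Sound Screening for Valvular Heart Disease from Four-Position Phonocardiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An auscultation-based screening pipeline for left-sided valvular
    heart disease. Conditions four-position phonocardiogram recordings (spike
    removal, anti-aliased downsampling to 2205 Hz), segments the cardiac cycle
    with a duration-dependent hidden semi-Markov model using a multi-recording
    heart-rate estimate, extracts standardized 13x200 MFCC blocks over four-cycle
    windows, and regresses murmur grade with a two-layer LSTM network. Predicted
    grades from the four auscultation positions feed a BIC-selected multiposition
    linear model of the aortic valve mean pressure gradient, clinical-variable
    logistic fusion models, and a cross-validated screening harness with
    exact binomial and fold-based confidence intervals. Includes a seeded
    synthetic cohort generator emulating the statistical structure the analysis
    assumes, so every stage is testable without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
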