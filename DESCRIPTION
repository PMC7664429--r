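Package: edaffect
Title: Electrodermal Activity Feature Extraction and Two-Class Emotion Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for evaluating emotional state from wrist-worn
    electrodermal activity (EDA) recordings paired with the Job-related
    Affective Well-being Scale (JAWS) questionnaire. Reads Empatica-E4-style
    conductance and event-marker CSV files, segments recordings into exercise
    windows, denoises them with a capped-level Symlet wavelet transform,
    splits tonic and phasic components, detects skin conductance responses
    from the phasic derivative, and computes a battery of per-segment
    statistical and event features. Features are reduced by coefficient of
    variation and univariate two-cluster within-cluster-sum-of-squares
    criteria, participants are partitioned into two emotion classes by
    agglomerative hierarchical clustering or k-means (optionally after PCA),
    and agreement with questionnaire-derived and expert reference labels is
    scored by accuracy, sensitivity and specificity. A synthetic cohort
    generator with a latent two-class structure makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
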