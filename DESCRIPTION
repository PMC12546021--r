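Package: ewtqc
Title: Withdrawal Quality Control for Colonoscopy Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-level quality control for the withdrawal phase of
    colonoscopy. Classifies frames (ileocecal landmark, instrument
    operation, normal mucosa), detects blurred frames from the variance of
    the Laplacian response, monitors withdrawal speed from the Hamming
    distance between perceptual hashes of consecutive frames, and
    accumulates withdrawal time (WT), instrument time (Time 1),
    non-interpretable time (Time 2) and effective withdrawal time
    (EWT = WT - Time 1 - Time 2). Includes a seeded synthetic-video
    generator with a ground-truth timeline for end-to-end testing,
    classifier evaluation metrics (sensitivity, specificity, precision,
    accuracy, F1, AP, AUC, weighted averages), rater-agreement statistics
    (ICC(A,1), Bland-Altman limits of agreement, Pearson r, Wilcoxon
    signed-rank), live-overlay rendering and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
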