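Package: pulsegate
Title: Remote-Photoplethysmography Face Anti-Spoofing on Synthetic Pulsatile Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for face presentation-attack detection from the
    remote photoplethysmography (rPPG) signal alone. Generates synthetic
    pulsatile face videos with known heart rate and attack type (cut-off photo,
    high-quality replay, shaking, bending, moving light), screens videos for
    gross motion and luminance changes via sparse optical flow, extracts
    per-region pulse signals with the CHROM chrominance method
    (YCbCr skin masking, smoothness-priors detrending, Butterworth band-pass,
    Hann-windowed spectral heart-rate estimation), segments the five signal
    channels of three face regions into 90-frame clips, and classifies clips
    as genuine or attack with compact LSTM, CNN and CRNN models, including a
    per-signal separate-branch fusion variant. Ships a command-line interface
    and ROC/AUC evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    png,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
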