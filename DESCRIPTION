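Package: cionaswim
Title: Quantification of Ciona Larval Swimming Behavior from Tracked Midlines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end quantification of Ciona intestinalis larval swimming
    from tracked 49-point midline skeletons: per-frame posture featurization
    (neck detection, seven-segment partition, Savitzky-Golay curvature,
    relative tangent angles, quirkiness, segment speeds), eigenposture
    decomposition of the curvature covariance ("eigencionas") with per-frame
    eigencoefficients, multidimensional matrix-profile motif discovery with
    time-series k-means clustering, Gaussian hidden Markov model behavioral
    state segmentation with Viterbi decoding and per-condition transition
    matrices, Morlet-wavelet behavioral-space mapping (composite t-SNE
    embedding, density clustering, k-nearest-neighbor assignment), and the
    associated nonparametric statistics (standardized median differences,
    Wilcoxon and Mann-Whitney batteries, light-stimulus event-window
    analysis). Includes a synthetic larval-swim generator with full ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
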