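Package: echoclass
Title: Differentiation and Classification of Odontocete Echolocation Clicks
Version: 0.1.0
Authors@R: person("Echoclass", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A passive-acoustic-monitoring analysis pipeline for separating
    beluga (Delphinapterus leucas) and narwhal (Monodon monoceros)
    echolocation clicks. Provides a calibrated synthetic click-train
    simulator, a Teager-Kaiser energy click detector with frequency-bin
    detector codes, extraction of twenty spectral and temporal click
    parameters (peaks, notches, -3/-10 dB band edges, Q, duration,
    inter-click interval), event-level aggregation, permutational MANOVA and
    dispersion tests with broken-stick PCA, a balanced without-replacement
    random-forest event classifier with out-of-bag evaluation, and a
    two-stage (call + event) classifier with encounter-similarity
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
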