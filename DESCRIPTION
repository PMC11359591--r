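Package: beebuzz
Title: Acoustic Discrimination of Drone and Worker Honeybees by
    Autoencoder Reconstruction Error
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects drone honeybees in flight audio recorded at the hive
    entrance, treating the drone buzz as an anomaly relative to the far more
    common worker buzz. Provides four frequency-domain feature extractors
    (Burg autoregressive power spectral density, MUSIC pseudospectrum,
    mel-frequency cepstral coefficients, gammatone cepstral coefficients),
    a bottlenecked autoencoder trained on worker audio only, k-sigma
    decision thresholds on the reconstruction error, and an empirical-Bayes
    maximum-likelihood threshold obtained from Gaussian fits to the two
    classes' error distributions. Includes a seeded synthetic buzz
    generator so the whole pipeline is testable without field recordings,
    plus WAV segmentation utilities and an experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
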