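Package: preictal
Title: Bispectral Features and Seizure-Wise Classification for Intracranial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Higher-order spectral analysis of multichannel intracranial EEG
    for seizure prediction. Estimates the bispectrum of 30-second recording
    windows by the direct FFT method, extracts the mean bispectral magnitude
    (Mave) and the normalized bispectral entropies (P1, P2) over the
    non-redundant frequency region, tests preictal-versus-interictal feature
    differences globally (one-way ANOVA) and per seizure and channel
    (Mann-Whitney U, summarized as a percent-of-predictable-seizures map),
    and classifies windows with a five-layer multilayer perceptron trained
    under a leakage-free seizure-wise data split. A synthetic-data module
    generates multichannel recordings with state-dependent quadratic phase
    coupling so the full pipeline runs without any external recordings; a
    minimal EDF reader provides an input path for real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    tibble,
    digest,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
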