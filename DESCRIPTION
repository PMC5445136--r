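Package: painsense
Title: Pain Intensity Recognition from Multi-Channel Physiological Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying electrically induced pain
    intensity (four levels: baseline plus 20/30/40 mA stimulation) from blood
    volume pulse (BVP), electrocardiogram (ECG) and skin conductance level
    (SCL) recordings. Provides a stimulus-locked synthetic-signal generator
    emulating the acquisition protocol, per-channel preprocessing (Butterworth
    band-pass, high-pass plus moving-average smoothing, baseline correction,
    decimation), sliding-window extraction of twelve statistical features per
    channel, wrapper feature selection by a steady-state genetic algorithm
    hybridised with principal-component reduction, one-vs-rest linear
    discriminant, distance-weighted k-nearest-neighbour and radial-basis
    support vector classifiers, and evaluation scenarios covering
    single-signal, multi-signal, multi-subject, leave-one-subject-out and
    leave-one-day-out designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    optparse,
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
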