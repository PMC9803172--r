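Package: gliastate
Title: Joint Morphology and Fluorescence-Lifetime Classification of Microglia Activation State
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies microglia as resting (ramified) or activated (amoeboid)
    from per-cell segmentation masks and time-correlated single photon counting
    (TCSPC) fluorescence-lifetime decay stacks. Implements four shape-descriptor
    families (Zernike moments, chord-length histograms, elliptic Fourier
    descriptors, general geometric features), a bidirectional LSTM over binned
    per-component photon-count histograms, and a fused network trained with
    stochastic gradient descent, together with cross-validation and ablation
    harnesses, kernel canonical correlation analysis with a Wasserstein-distance
    lifetime kernel, and a synthetic-data generator emulating class-conditional
    morphology and bi-exponential decay kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
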