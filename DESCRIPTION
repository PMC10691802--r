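Package: cuedecide
Title: Analysis of Cued Perceptual Decision Experiments with Drift
    Diffusion Modeling and EEG Decision Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for pharmacological
    spatial-attention studies of perceptual decision-making. Generates
    balanced cued orientation-discrimination session designs and weighted
    up-down adaptive staircases; simulates and fits drift diffusion models,
    including an exact Wiener first-passage-time likelihood and a
    hierarchical Bayesian accuracy-coded regression model with weighted
    effect coding; computes signal-detection and reaction-time summaries;
    derives EEG decision markers (centro-parietal positivity peak and
    build-up rate, contralateral/ipsilateral ERPs, surface-Laplacian
    current source density, Morlet time-frequency power and alpha-band
    lateralization); provides cluster-corrected permutation repeated-
    measures ANOVAs and one-sample tests; and derives physiological
    measures (mean arterial pressure, visual-analogue-scale categories,
    pupil preprocessing). A synthetic-data generator emulating the full
    study structure makes every stage testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
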