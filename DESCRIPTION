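Package: faabayes
Title: Frontal Alpha Asymmetry, Pupillometry and Bayes Factor Inference
    for Auditory Consumer-Neuroscience Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse small-sample consumer-neuroscience experiments
    in which participants listen to commercial scripts while EEG and pupil
    diameter are recorded. Implements spectral extraction of frontal and
    parietal alpha asymmetry (single-bin FFT power with decibel baseline
    normalisation), CHAP-style pupillometry preprocessing (eye merging,
    epoch splitting, z-score outlier rejection, blink interpolation,
    baseline-relative change), composite attitude and investment scoring,
    default Bayes factor hypothesis tests (JZS Cauchy-prior t tests and
    Savage-Dickey Kendall tau-b correlations with stretched-beta priors)
    with prior-width robustness analysis, and a Bayes-factor multiplicity
    correction built from the Vovk-Sellke bound and Benjamini-Hochberg
    critical values. A synthetic-cohort generator with known ground truth
    (Gaussian-copula behavioural coupling, configurable hemispheric alpha
    power ratios) makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
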