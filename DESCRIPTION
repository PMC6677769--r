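Package: flexreadout
Title: Linking Models for Flexible Cortical Readout of Motion Visibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses two-feature (contrast and motion coherence)
    two-alternative forced-choice discrimination experiments with concurrent
    event-related BOLD measurements. Provides a synthetic task and observer
    generator (PEST adaptive staircases, catch trials, exponential inter-trial
    intervals, linear hemodynamic summation), psychometric fitting
    (cumulative-normal and Weibull maximum likelihood, lapse estimation, Weber
    slopes), finite-impulse-response deconvolution of BOLD timeseries with
    canonical-HRF amplitude reduction and population response function fitting
    (Naka-Rushton contrast, saturating-exponential coherence), probit linking
    models that read out weighted cortical area responses with fixed or
    task-flexible weights (plus choice-history, efficient-selection, and
    Poisson-noise variants), analytic just-noticeable-difference prediction,
    and cross-validated model comparison with Tjur's coefficient of
    discrimination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
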