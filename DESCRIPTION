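Package: icdyn
Title: Spike-Train Dynamics, Reward Contrasts and Detection Probability for
    Auditory Oddball Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-unit spike trains recorded during an
    auditory duration-deviation (oddball) task and a block-wise reward
    protocol, together with a seeded synthetic-session generator so every
    analysis can be validated against a known ground truth. Implements
    event-aligned peri-stimulus time histograms, windowed firing rates, the
    Response Dynamic Index quantifying late-window "climbing" activity,
    stimulus-order response profiles, reward-responsiveness classification
    and reward-prediction-error contrasts, cumulative-Gaussian psychometric
    fitting with behavioural quality control, and ROC-based detection
    probability with a permutation null. Sessions are stored in a documented
    JSON schema; results are tidy tibbles.
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
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
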