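Package: thumbscreen
Title: Tablet-Based Thumb-Reach Screening for Carpal Tunnel Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses twelve-direction thumb-reach sessions
    recorded on a touchscreen for carpal tunnel syndrome (CTS) screening.
    Segments raw touch streams into per-direction reaches, extracts the
    36-value kinematic feature vector (maximum speed, average speed and
    total time per clock direction), compares CTS and non-CTS groups with
    Welch tests and bootstrap confidence intervals for medians, and screens
    hands with a grid-search-tuned support vector machine evaluated by
    leave-one-out cross-validation. A seeded synthetic-cohort generator
    produces full touch streams whose group medians follow configurable
    impairment profiles, so the whole pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
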