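Package: fosnet
Title: Regional c-Fos Coactivation Networks and Behavioral Scoring for
    Conditioned Taste Aversion Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds significance-thresholded Pearson correlation networks of
    per-subject regional c-Fos counts, and differential (subtraction) networks
    obtained by Fisher r-to-z transformation, z-score subtraction of a control
    condition, back-transformation, and re-testing with t = r*sqrt(n-2)/sqrt(1-r^2).
    Also implements behavioral scoring for conditioned taste aversion
    experiments: day-2/day-1 intake ratios, weight-adjusted intake, block-wise
    ultrasonic vocalization scoring with emitter tallies, and time-sampled
    nausea behavior scoring. A seeded synthetic-data generator with planted
    correlation structure makes every pipeline stage testable without access
    to per-subject raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    MASS,
    Matrix,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
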