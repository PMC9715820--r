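Package: hfamc
Title: Absorbing Markov Chain Models of Chronic Heart Failure Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dynamic risk stratification for chronic heart failure service
    populations using discrete-time absorbing Markov chains. Patient event
    histories (clinic visits, heart failure hospitalizations, death) are
    discretized into five health states over consecutive 4-month cycles;
    transition matrices are estimated from the first two transitions and
    assembled into a canonical absorbing chain from which the fundamental
    matrix, expected cycles to absorption, absorption probabilities and
    forward state-distribution predictions are derived and validated against
    observed distributions. A seeded synthetic cohort generator emulates
    registry-style event logs from a configurable ground-truth chain so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
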