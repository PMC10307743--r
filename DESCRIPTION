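Package: rtresponse
Title: Tumour Growth and Fractionated Radiotherapy Response Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates solid tumour response to fractionated radiotherapy with
    a four-variable dimensionless ordinary differential equation model that
    distinguishes nutrient-limited from space-limited growth control.
    Provides the time-dependent radiation damage/repair dynamics, Monday to
    Friday fractionation schedules with a total-dose cap, closed-form and
    numerical steady-state analysis (nutrient-limited, space-limited and
    bistable regimes, the V_N and V_S vascular thresholds and the V_d
    proximity index), piecewise integration with a compiled right-hand
    side, seeded virtual tumour cohorts, and last-week response metrics
    (Delta_viable, Delta_total, composition percentages, post-treatment
    attractor classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
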