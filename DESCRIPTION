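Package: hymn
Title: Hydrophobically Gated Memristive Nanopores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models hydrophobically gated nanopores that behave as iontronic
    memristors. Builds capillarity (classical nucleation theory) and tabulated
    filling free-energy profiles, applies an electrowetting voltage tilt,
    converts barriers into voltage-dependent wetting and drying rates
    (Arrhenius or mean first-passage time), integrates the two-state master
    equation and stochastic pore arrays under arbitrary voltage protocols to
    produce pinched-hysteresis current-voltage loops, classifies pore
    geometries against the four memristor design criteria on diameter by
    aspect-ratio maps, and implements the electrophysiology processing chain:
    membrane-capacitance subtraction, cycle-averaged IV loops, hysteresis and
    polarity metrics, and random-telegraph dwell-time statistics. A synthetic
    data generator provides ground-truth recordings for validation.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
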