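Package: thermoclock
Title: Temperature Entrainment of Peripheral Circadian Clocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the entrainment of peripheral circadian clocks by
    square-wave temperature rhythms with a semi-mechanistic ordinary
    differential equation model: a thermosensing cascade feeds an HSF1/HSP
    heat-shock-response module that drives a clock gene network. Provides
    single-cell and heterogeneous-population simulation under constant,
    rhythmic and alternating "shift-work" temperature schedules, Sobol
    quasi-random population sampling, peak-based phase and period
    extraction, the mean-field synchronization index R_syn, the standard
    in-silico experiments (rhythm on/off validation, amplitude and mean
    sweeps, Arnold entrainment grid, shift-schedule adaptation) and an
    individualized-response sensitivity regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    digest,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
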