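Package: oncoaddict
Title: Stochastic Multi-State Simulation of Tumor Regression and Relapse
    after Oncogene Inactivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the population dynamics of oncogene-addicted tumors
    under conditional (tetracycline-controlled) MYC expression.  Tumor cells
    occupy one of six states (MYC on, MYC off, apoptosis-committed,
    differentiated, senescent, escaped) with first-order probabilistic
    transitions advanced by fixed-step Euler integration; apoptosis removes
    cells only after a commitment-to-death delay implemented as a FIFO
    cohort queue.  Provides a seeded stochastic engine with multinomial
    per-state draws, a mean-field deterministic engine for the same model,
    named scenario presets (regression with and without delay, relapse in
    immunodeficient hosts, replicate ensembles), summary metrics for
    regression and relapse kinetics, rate-sensitivity sweeps, tidy
    trajectory output, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
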