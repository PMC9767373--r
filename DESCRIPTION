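Package: probegng
Title: Reinforcement-Learning Analysis of Go/No-Go Learning Under
    Intermittent Reinforcement Removal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying instrumental go/no-go learning when
    reinforcement is intermittently withheld. Generates deterministic
    go/no-go task schedules with interleaved non-reinforced probe blocks,
    simulates behaviour from Q-learning agents with a biased softmax choice
    rule (four variants: baseline, temperature, bias, full), computes
    signal-detection measures (hit and false-alarm rates with ceiling
    corrections, d-prime, criterion c) over sliding windows and
    probe-block contrasts, fits the models by multi-start maximum
    likelihood with BIC comparison and a fixed-learning-rate sweep, and
    provides parameter-recovery and model-validation harnesses that run on
    synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
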