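Package: lexcon
Title: Word Length, Frequency and Surprisal Effects on Eye-Movement Reading Times
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for analysing how word length, word frequency and
    surprisal shape eye-movement reading times in native (L1) and non-native
    (L2) readers. Annotates word-level fixation reports with the three
    benchmark word properties, reduces fixation event streams to first
    fixation, gaze duration and total fixation measures, fits penalized
    cubic-regression-spline additive models with participant random effects,
    computes per-participant average slowdown effects and the
    frequency-surprisal (lexicon-context) tradeoff, tests how effect sizes
    relate to L2 proficiency, and runs a subjective-probability sample-size
    simulation. Ships a seeded synthetic-data generator (Zipfian bigram
    corpora, participant profiles, reading times with spillover and random
    effects) so the whole pipeline is testable without external eye-tracking
    data.
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
    mgcv,
    purrr,
    readr,
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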