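Package: switchwave
Title: Slow and Fast Switcher Analysis of Sleep Slow Waves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sleep slow waves and spindles in multichannel NREM EEG,
    computes each wave's transition frequency (the inverse of twice the delay
    from the hyperpolarization trough to the depolarization peak), classifies
    waves into slow and fast switchers with a two-component Gaussian mixture
    selected by AIC, quantifies event-locked phase-lag-index connectivity at
    six phases of the depolarization transition with a max-statistics
    permutation null, and models the across-cycle exponential decline of each
    switcher class. Includes a seeded synthetic polysomnography generator with
    ground-truth annotations so the full pipeline is testable without clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
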