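Package: phenomatch
Title: Phenological Match/Mismatch Analysis for a Truncated Predator Population
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for studying how age-size truncation of a
    predator population alters the effect of predator-prey phenological
    mismatch on recruitment and population variability, modelled on a
    long-term lake fish-zooplankton monitoring system. Provides Gaussian
    phenology-curve fitting to weekly count data, a degree-day
    egg-development model that propagates spawning phenology to larval
    hatching, a signed match/mismatch index, declarative linear-model
    specification with centred quadratic and dummy-interaction terms,
    leave-one-year-out cross-validation backward selection with AICc
    cross-check and residual diagnostics, sliding-window
    coefficient-of-variation analysis of abundance series, and a synthetic
    lake-system data generator for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
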