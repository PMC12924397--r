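Package: movescale
Title: Temporal-Scale Validation of Hidden Markov Model Behavioural States
    from GPS Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test how reliably hidden Markov models (HMMs) fitted to
    GPS movement tracks recover animal behavioural states, and how sensitive
    those inferences are to the GPS relocation interval. Simulates
    behaviour-switching tracks with co-registered instantaneous behaviour
    labels (emulating collar video clips), splits fix tables into
    constant-interval bursts, resamples them to coarser intervals by retaining
    every nth location, fits two- and three-state HMMs with gamma step-length
    and von Mises turn-angle state-dependent distributions by multi-start
    maximum likelihood, decodes states with the Viterbi algorithm, bins raw
    behaviour labels to matching broad categories under single-label and
    multi-label dialects, and quantifies state-versus-label agreement,
    cross-scale state agreement, and apparent behavioural bout durations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    caret,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
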