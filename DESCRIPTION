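Package: itmemory
Title: Predicting Single-Exposure Visual Recognition Memory from
    Inferotemporal Spike Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether repetition suppression in
    inferotemporal (IT) cortex can account for single-exposure visual
    recognition-memory behavior. Implements forgetting-function and
    reaction-time summaries of novel/familiar trial tables, n-back-aligned
    pseudopopulation construction with cross-validated resampling, four
    linear population decoders (Fisher linear discriminant and spike-count
    classifier, each with d'-ranked unit selection), strength-theory
    reaction-time prediction, a step-benchmarked prediction-quality score,
    Gaussian extrapolation of decoder performance to larger populations,
    bootstrap statistics, and a seeded synthetic-data generator that
    emulates the task structure and the statistical structure of IT
    spike-count recordings so that every stage is testable without
    recorded data.
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
    minpack.lm,
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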