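Package: divpoint
Title: Divergence Point Analysis for Response-Latency Distributions
Version: 0.1.0
Authors@R:
    person("divpoint", "maintainers", email = "divpoint@example.org",
           role = c("aut", "cre"))
Description: Bootstrap-based estimation of the earliest discernible onset of
    an experimental effect on response-latency distributions (fixation
    durations, reaction times). Implements the original group-level
    divergence point analysis (DPA) over empirical survival curves, the
    Confidence-Interval DPA that attaches a percentile confidence interval
    to the onset estimate, and the Individual-Participant DPA based on
    paired order statistics of bootstrap resamples. Includes ex-Gaussian
    synthetic-data generators with injectable known divergence points, a
    simulation harness for participant- and observation-subsampling
    parameter-recovery studies, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
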