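Package: tdsboot
Title: Bootstrap Uncertainty Bands for Temporal Dominance of Sensations Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for temporal dominance of sensations (TDS) data: task-level
    data structures and input/output, dominance-proportion (TDS) curves on a
    normalized time grid, bootstrap resampling of whole tasks with
    order-statistic 95% confidence and standard-error bands, binomial
    normal-approximation bands, a phase-dependent Markov-chain simulator of
    TDS tasks with an exact analytic calculator of population dominance
    proportions, and a Monte Carlo coverage (inclusion-probability) study that
    validates the estimated uncertainty bands against a known population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
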