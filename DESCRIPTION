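Package: depvox
Title: Speaker-Level Depression Screening from Speech with Ensembles of
    One-Dimensional Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for binary depression screening from
    interview speech. Long per-speaker recordings are cropped into 4-second
    samples under a class-balanced sampling plan, represented as min-max
    normalized log-spectrograms, and classified by one-dimensional
    convolutional networks whose filters span the whole frequency axis.
    Per-sample probabilities are aggregated to speaker-level decisions, and
    ensembles of identically configured, differently initialized networks
    are fused by probability averaging or label modes. Includes a synthetic
    interview-corpus generator with a controllable class effect, speaker
    metrics (per-class F1, precision, recall), speaker-disjoint
    cross-validation, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
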