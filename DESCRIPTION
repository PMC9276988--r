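Package: spsp
Title: Spherical Phase-Space Partitioning for Symbolic Analysis of
    Multichannel Physiological Signals
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts multichannel physiological recordings (e.g., 32-channel
    EEG trials) into symbol sequences by treating each sample as a point in
    channel space, measuring its Euclidean distance from the trajectory mean
    (the hypersphere centre), and discretising the distance series with
    uniform or maximum-entropy partitioning.  The alphabet size is selected
    by a Shannon-entropy increment rule.  Emotional (or other) states are
    classified by maximum cosine similarity to per-class template sequences
    under leave-one-subject-out cross-validation.  Includes delimited-text /
    JSON-manifest dataset I/O, a class-conditional synthetic-data generator,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
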