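Package: jgrs
Title: Multi-Phase Structured Pruning for Compact Neural Decoding Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structured pruning of multi-layer perceptron and convolutional
    classifiers used in calcium-imaging-based neural decoding. Implements the
    jump greedy-random-selection (JGRS) multi-phase pruning schedule, which
    batches unit removals during an early "far phase" where accuracy is
    insensitive to structural change and falls back to per-unit greedy random
    selection (GRS) near the final compact structure, together with random
    (RRS) and weight-magnitude (NWM) baselines, pruning comparison metrics,
    and seeded synthetic generators emulating calcium-trace and
    graph-embedding decoding datasets. Models support weight-preserving unit
    surgery with exact parameter and FLOP accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
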