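Package: ciliabeat
Title: Quantification of Ciliary Beating from High-Speed Video Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and quantifies the beating of single isolated
    (demembranated) airway cilia as recorded by high-speed video microscopy
    at 250 frames per second. A seeded generator produces ground-truth beat
    trajectories (fast effective stroke, slower recovery stroke, lognormal
    rest intervals) and renders them into realistic grayscale image stacks;
    a line-scan (kymograph) quantifier recovers the ciliary beat frequency
    (CBF), ciliary bend distance (CBD), stroke durations and inter-beat
    intervals; cohort-level summaries, ratios normalized to a reference
    condition, and significance tests reproduce pH and ATP dose-response
    analyses entirely from synthetic data, so every stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    tiff,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
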