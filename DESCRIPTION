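Package: tagflight
Title: Call Detection Evaluation and Dive Discrimination for Acoustic Biologgers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for animal-borne sound-and-movement tags
    ('biologgers') deployed on birds. Evaluates vocalization detections
    against human annotations by one-to-one interval intersection-over-union
    matching with per-class and macro-averaged precision, recall and F1;
    measures call levels in dBFS and per-call signal-to-noise ratios with a
    nearest-clean-noise-window rule; decomposes tri-axial acceleration into
    static and dynamic components with a zero-delay FIR high-pass, segments
    flight bouts, detects banking peaks that distinguish anti-predatory
    dives from ordinary flight, and tests the association with an exact
    two-sided Fisher test. A seeded synthetic-data generator produces
    soundscapes, detection scenarios and acceleration traces with known
    ground truth so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
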