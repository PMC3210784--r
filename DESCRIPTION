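Package: trackvalidatr
Title: Validated Overlap-Based Cell Tracking for Label-Free Time-Lapse
    Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tracks unlabeled adherent cells through time-lapse micrograph
    stacks by mask overlap, detects mitoses from their morphological
    signature (shrinking, rounding, brightening), and validates the
    resulting cell paths with a systematic error-classification decision
    tree that accepts only trustworthy complete (mitosis-to-mitosis)
    paths. Includes evaluation metrics against reference data (detection
    and genealogy false acceptance/rejection rates, tracking
    trustworthiness), automated extraction of culture parameters
    (proliferation, confluency, life-time distribution, sibling
    symmetry), and a seeded synthetic time-lapse simulator with
    pixel-exact ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    optparse,
    withr
Config/testthat/edition: 3
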