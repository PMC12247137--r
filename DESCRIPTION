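Package: drgmodal
Title: Classification of Pain- and Itch-Responsive DRG Neurons from Calcium
    Imaging and Single-Cell Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for classifying dorsal root ganglion (DRG)
    sensory neurons as pain-, itch-, or dual-responsive from two arms of
    evidence: in vivo two-photon calcium recordings (delta-F/F0 transient
    detection with a fixed activation criterion, stimulus-overlap statistics,
    and population amplitude comparisons) and single-cell UMI count matrices
    (quality-control filtering, fraction-of-positive-cells marker thresholding
    at 5 percent of the top-three-cell maximum, and Wilcoxon rank-sum
    differential expression with fold-change and detection filters). Includes
    seeded synthetic-data generators for both arms with planted ground truth,
    so every step is testable without raw imaging or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
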