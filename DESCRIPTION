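Package: annotriplet
Title: Difficulty, Uncertainty and Agreement Analysis for Similarity-Based
    Triplet Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse similarity-based triplet annotation
    experiments, in which annotators assign an unlabeled medical record to
    the more similar of two labeled anchor records. Implements the
    Artificial Similarity-Based Annotator (a deterministic nearest-neighbour
    annotator over the Heterogeneous Euclidean-Overlap Metric with a
    distance-ratio uncertainty score), correctness and stated-uncertainty
    quantifications, per-task agreement measures and nominal-scale
    Krippendorff's alpha, electrodermal-activity segmentation with
    10-second-sampled means, a mixed-model association suite with
    per-annotator random intercepts, and configurable generators for
    synthetic cohorts, annotator behaviour and electrodermal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
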