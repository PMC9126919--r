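Package: retellr
Title: Temporal Compression in Verbal Retelling and Encoding-to-Recall
    Pattern Transformation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for naturalistic free-recall fMRI studies in
    which participants watch a continuous movie and later retell it aloud.
    Codes recall utterances for temporal precision (Summary vs Temporally
    Precise) from their mapped movie-segment spans, computes temporal
    compression factors and scene-level summary-bias scores, validates the
    coding with text-embedding cosine similarity, measures within-subject
    encoding-to-recall reinstatement at the micro-segment level, computes the
    inter-subject memory-transformation statistic (recall-to-recall minus
    movie-to-recall pattern similarity) with scene-label permutation tests
    and FDR masking, and links per-subject summary bias to scene-level
    transformation with random-effects inference. Includes a calibrated
    synthetic-data generator (segmentations, transcripts, parcel-wise voxel
    patterns with a shared movie component and event-specific shared recall
    shifts) with exported ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    RNifti,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
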