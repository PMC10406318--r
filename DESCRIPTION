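Package: sysdecode
Title: Systems-Level Meta-Analytic Decoding of Seed-Cortical Co-Activations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Coordinate-based Bayesian reverse-inference decoding of brain
    regions against a study/term database, seed-based resting-state
    functional connectivity with voxel-level family-wise error control,
    joint seed-region co-activation decoding with set-difference logic,
    aggregation of decoded terms into topics, and quantitative overlap of
    the resulting topic maps with canonical intrinsic-network partitions.
    Includes a synthetic-data generator that emulates every required input
    (probabilistic seed maps, cortical parcellations, multi-subject BOLD,
    coordinate databases, topic mappings) at toy scale with planted ground
    truth, so the full pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
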