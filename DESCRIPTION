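Package: nfkbtrace
Title: Single-Cell NF-kB Nuclear-Translocation Dynamics from Synthetic
    Two-Channel Time-Lapse Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and quantifies NF-kB (p65 reporter) nuclear
    translocation in single cells. A phenomenological response model
    generates heterogeneous single-cell nuclear-localization time courses
    for three lipopolysaccharide preparations (with Hill-type
    fraction-active dose-response and a soluble-TNF-receptor blocking
    modifier), a renderer turns cell populations into noisy two-channel
    time-lapse movies with exported ground truth, and an image-analysis
    pipeline (nuclear segmentation, tracking, trace extraction) recovers
    per-cell peak amplitude, time-to-peak and peak width, plus population
    summaries: fraction-active dose-response curves and cosine-distance
    similarity matrices of average activation time courses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
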