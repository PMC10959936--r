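Package: tlsquant
Title: Segmentation-Based Quantification of Tertiary Lymphoid Structures on H&E Slides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tertiary lymphoid structures (TLSs) on hematoxylin and
    eosin stained histology slides. The pipeline tiles a slide into 512x512
    windows, masks tissue with Otsu thresholding and pen-mark colour filters,
    segments TLS-like lymphocyte aggregates with a trainable pixelwise
    segmenter (or an oracle for validation), counts lymphocytes with a
    pluggable nucleus detector, and accumulates the per-slide TLS ratio
    (TLS area over tissue area). Includes a synthetic slide and cohort
    generator with exact ground truth, segmentation evaluation metrics
    (Dice, IoU, pixel-level AUC with tile bootstrap), and the downstream
    survival statistics applied to the TLS-ratio biomarker (maximally
    selected log-rank cutpoint, Kaplan-Meier and log-rank comparison, Cox
    proportional-hazards models with Harrell's C, nested likelihood-ratio
    tests, Wilcoxon responder comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    survival,
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
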