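Package: neuromaturity
Title: High-Content Neuronal Maturation Assay and Screen Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-phenotypic quantification of neuronal maturation from
    high-content imaging and electrophysiology. Implements nucleus
    segmentation and morphometry, automated neurite tracing, depolarization-
    induced immediate-early-gene scoring and synaptic puncta apposition;
    plate-level b-score and robust z-score normalization with PCA-based hit
    selection for compound screens; spike, network-burst and calcium-transient
    detection for multielectrode-array and calcium-imaging recordings; and a
    synthetic-data generator with planted ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
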