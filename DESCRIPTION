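Package: sijbme
Title: Detection of Sacroiliac Bone Marrow Edema on MR Slices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for detecting bone marrow edema (BME) on sacroiliac-joint
    (SIJ) MR slices and diagnosing active sacroiliitis per subject. Provides a
    synthetic SIJ phantom generator with ground-truth annotations, ROI patch
    construction from iliac bounding boxes, scanner-noise injection, a
    convolutional slice classifier trained with focal loss and a cosine
    learning-rate schedule, size-3 median-filter correction of per-subject
    slice prediction sequences, subject-level diagnostic aggregation under the
    ASAS positivity rule, confusion-matrix metrics with ROC/AUC and repeated
    subject-wise hold-out evaluation, and Grad-CAM saliency maps for visual
    validation of positive classifications.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    pROC,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
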