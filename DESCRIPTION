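Package: dermaCAD
Title: Computer-Aided Diagnosis of Melanoma from Skin Lesion Images
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-aided diagnosis (CAD) pipeline for classifying
    pigmented skin lesion photographs as melanoma or nevus. Implements
    median-filter and bottom-hat based hair-artifact removal, multi-stage
    lesion segmentation (per-channel Otsu thresholding, mask fusion,
    morphological cleanup, iterative median smoothing, size filtering and
    contour tracing), four handcrafted lesion descriptors (local binary
    patterns, a 24-neighbour LBP extension, histograms of oriented
    gradients, and a small-cell HOG variant), three classifiers (Gentle
    AdaBoost with weighted-least-squares regression stumps, k-nearest
    neighbours, and a radial-basis-function support vector machine), and a
    stratified cross-validation harness with class balancing by random
    over-sampling and the standard diagnostic statistics (accuracy,
    sensitivity, specificity, PPV, NPV). A seeded synthetic lesion-image
    generator with ground-truth masks makes the whole pipeline testable
    without any external image set.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    tools,
    stats,
    utils,
    Matrix,
    png,
    jsonlite,
    e1071
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
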