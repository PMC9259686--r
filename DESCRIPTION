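Package: artseg
Title: Weakly Supervised Artifact Segmentation for Brightfield Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and segments visual artifacts (dust, fibres, debris,
    clumps) in brightfield cell-microscopy images using only image-level
    clean/artifact labels. A small convolutional classifier is trained on
    the weak labels, Score-CAM saliency maps localize the artifacts, and
    binarized saliency maps serve as pseudo-labels to train a U-Net pixel
    segmenter (the ScoreCAM-U-Net scheme). Includes clean-image synthesis
    by second-order polynomial background estimation and noise-profile
    inpainting, a synthetic brightfield data generator with ground truth,
    segmentation evaluation metrics (pixel-, object- and image-level), and
    downstream impact analyses: artifact-stratified nuclei scoring, nucleus
    morphometry, artifact-excluded fluorescence quantification and
    Hill-equation concentration-response (IC50) regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    minpack.lm,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
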