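Package: mdtwposture
Title: High-Knee-Flexion Posture Recognition with Multi-Dimensional
    Dynamic Time Warping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Template-based recognition of twelve high-knee-flexion
    occupational postures (kneeling, squatting, sitting, stooping,
    standing and walking variants) from six lower-limb flexion-extension
    joint-angle time series. Trials are time-normalized to 101 samples
    and scale-normalized to [-1, 1]; per-joint dynamic time warping
    distances under a Sakoe-Chiba band are fused by a weighted sum into a
    multi-dimensional distance driving a k-nearest-neighbour classifier.
    Includes stratified holdout and five-fold cross-validation with grid
    searches over the band half-width, k and channel weights,
    confusion-matrix metrics (sensitivity, specificity, balanced
    accuracy), gait-cycle segmentation, a synthetic kinematics generator
    for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
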