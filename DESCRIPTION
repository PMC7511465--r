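Package: mvseg
Title: Coarse-to-Fine Multi-View 2D Segmentation of Volumetric Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coarse-to-fine pipeline for segmenting the contrast-enhanced
    aortic lumen in volumetric computed tomography angiography. A first compact
    2D convolutional network localizes the vessel on strongly down-sampled
    axial slices; a fixed-size cuboid region of interest is then cropped at
    working resolution and segmented independently from axial, sagittal and
    coronal views; per-view probability stacks are smoothed along their
    stacking axis and fused by majority voting, probability averaging, or a
    combined rule. Includes Hounsfield windowing, voxel resampling, slice-level
    augmentation, a synthetic vascular phantom generator with ground-truth
    lumen masks for fully self-contained training and evaluation, and overlap
    (Dice, Jaccard) and symmetric surface-distance metrics based on exact
    Euclidean distance transforms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
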