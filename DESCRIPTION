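Package: risunet
Title: 2.5D Liver Tumor Segmentation with Res-Inception-SE U-Nets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for 2.5D liver tumor segmentation in abdominal CT. Implements
    a five-level encoder-decoder network whose convolution stages are
    Res-Inception-SE blocks (multi-scale Inception-style branches fused under
    squeeze-and-excitation channel attention with a residual projection), fed
    with stacks of n consecutive CT slices and supervised on the center slice.
    Includes the deterministic CT preprocessing pipeline (Hounsfield windowing,
    center cropping, histogram equalization, intensity normalization,
    tumor-slice filtering, 2.5D stack assembly), a hybrid Dice plus binary
    cross-entropy training objective, CPU training and inference with Adam,
    five segmentation quality metrics (Dice per case, volumetric overlap
    error, relative absolute volume difference, average and root-mean-square
    symmetric surface distance), and a seeded generator of low-contrast CT
    phantoms so the whole pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
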