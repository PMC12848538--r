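Package: dfatools
Title: Director Field Analysis of Diffusion Tensor Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric microstructure analysis of white matter from diffusion
    tensor imaging (DTI). Fits diffusion tensors from diffusion-weighted
    volumes, derives fractional anisotropy (FA) and mean diffusivity (MD),
    and computes the orientational distortion indices of the principal
    direction (director) field: splay, bend, twist, and their root-sum-square
    total distortion. Includes synthetic phantom generators (canonical
    distortion fields, diffusion-weighted signal simulation with Rician
    noise, label atlases, multi-group ROI-feature cohorts with known ground
    truth), permutation-based group inference with threshold-free cluster
    enhancement (TFCE) and family-wise error control, Spearman association
    analysis with false discovery rate correction, and a stratified
    cross-validated classification harness with fold-averaged ROC curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    nnet,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    igraph,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
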