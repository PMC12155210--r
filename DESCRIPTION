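Package: avcscore
Title: Aortic Valve Calcium Scoring in Non-Contrast CT with a Cylindrical Valve ROI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quantification of aortic valve calcification in
    non-contrast CT calcium-score volumes. Builds a parameterized cylindrical
    valve region of interest from a disk-like expert annotation via principal
    component analysis, or predicts it with a three-branch multi-task network
    (volumetric segmentation, latent-space parameter regression, and a
    differentiable cylinder-reconstruction loss with center-of-mass origin
    linkage). Applies Agatston criteria inside the region to obtain Agatston,
    volume, mass and lesion-count scores with sex-specific severity bins,
    performs noise quality control with median-filter denoising, and
    decomposes the cylinder into 9/27 shell-slab-sector sub-regions for
    regional calcification analysis. Includes a synthetic phantom generator
    so the full pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
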