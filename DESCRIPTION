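Package: lfdenoise
Title: Self-Supervised Denoising of Spatial-Angular Light-Field Microscopy Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised denoising for 4D spatial-angular (light-field)
    fluorescence microscopy stacks. Noisy training pairs are built from
    epipolar-plane-image (EPI) sub-stacks obtained by bidirectional angular
    traversal, plus orthogonal two-of-four pixel masks; a dual sub-network
    (3D U-net encoders with temporal and spatial transformer stages) and an
    attention-based fusion module are trained with composite L1/L2 losses and
    truncated-gradient fusion constraints. Includes a geometric light-field
    simulator with a Poisson-Gaussian camera model, a simplified iterative
    tomography reconstructor, image-quality metrics (MTF, RMSE, SSIM, PSNR,
    SNR, Pearson correlation) and calcium-trace analysis utilities
    (dF/F0, transient peak detection and width measurement). The neural
    network, reverse-mode autodifferentiation and Adam optimizer are
    implemented in R with C++ kernels for convolution and pooling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
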