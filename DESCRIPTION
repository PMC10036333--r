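Package: imcdenoise
Title: Hot-Pixel Removal and Self-Supervised Shot-Noise Filtering for
    Imaging Mass Cytometry
Version: 0.1.0
Authors@R:
    person("IMC", "Denoise Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage restoration of Imaging Mass Cytometry (IMC) ion-count
    images. Stage one (DIMR) removes hot-pixel outliers adaptively by
    building directional difference maps in the Anscombe domain and locating
    a detection threshold on a kernel density estimate of the aggregated
    difference statistic, with no user-set intensity threshold. Stage two
    (DeepSNiF) suppresses Poisson shot noise with a self-supervised
    blind-spot residual U-Net trained under an I-divergence loss with
    Hessian-norm regularization. Includes reference threshold-based
    hot-pixel filters and a Gaussian baseline, a synthetic IMC image
    simulator with ground-truth hot-pixel masks, a full image-quality metric
    suite (RMSE, PSNR, SSIM, STDB, CNR, PCC, F1, Jaccard), plain TIFF
    input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
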