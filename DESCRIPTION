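Package: tendondti
Title: Reliability and Repeatability Analysis of Tendon Diffusion Tensor
    Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to assess inter-rater reliability and test-retest
    repeatability of diffusion tensor imaging (DTI) scalar metrics in
    tendons. Provides a synthetic phantom cohort generator (curved
    elliptic-cylinder tendon masks, diffusion tensor fields, Rician-noise
    diffusion-weighted signals, simulated raters), per-voxel tensor
    fitting (weighted log-linear and damped nonlinear least squares) with
    eigenvalue, mean-diffusivity and fractional-anisotropy maps, tendon
    region-of-interest geometry (longest-diameter trisection into medial,
    central and lateral thirds, proximal/distal bisection, occupancy-based
    downsampling to the DTI grid, in-plane boundary erosion), long-format
    region statistics, and reliability statistics (consistency intraclass
    correlations from linear mixed models, participant bootstrap
    confidence intervals, standard errors of measurement, qualitative
    agreement classes, and ICC sample-size planning).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    lme4,
    minpack.lm,
    RNifti,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    EBImage,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
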