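Package: dent
Type: Package
Title: Diffuser-Elapser Surrogate Forecasting of Tumor Microenvironment
    Maps Under Combination Therapy
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a dimensionless reaction-diffusion model of the tumor
    microenvironment (tumor cell density, vasculature, interstitial fluid
    pressure, antiangiogenic agent and chemotherapy drug) under scheduled
    antiangiogenic plus chemotherapy combination treatment, builds paired
    image datasets from the simulated cases, and trains a composed
    convolutional surrogate -- two conditional drug-insertion networks
    ("Diffuser") plus five per-channel one-day forecasters ("Elapser") --
    that is rolled out autoregressively to forecast treatment response a
    week ahead.  Ships SSIM, PSNR and thresholded tumor-cell-density error
    metrics for evaluating predicted against simulated maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    grDevices,
    graphics,
    jsonlite,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
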