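Package: reefcarb
Title: Census-Based Coral Reef Carbonate Budgets with Cover Thresholds
    and Remote-Sensing Upscaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for census-based coral reef carbonate budget accounting
    from benthic line-intercept transects, sea-urchin quadrats, and
    parrotfish belt transects. Computes gross carbonate production from
    corals, crustose coralline algae and Halimeda; bioerosion by
    parrotfishes, sea urchins, and endolithic macro- and microborers; net
    carbonate production with a signed sedimentation term; and vertical
    reef-accretion potential. Includes a Bayesian additive mixed model
    (O'Sullivan penalized spline, Gibbs sampler) to estimate the live
    coral cover threshold for positive net production, a regression
    pipeline (collinearity screen, Cook's-distance outlier removal, PLSR
    component check, 70:30 train/test model selection) to upscale net
    production over a live-coral-cover raster, and seeded synthetic survey
    and raster generators with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    readxl,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
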