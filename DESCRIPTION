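Package: cctopo
Title: Connectivity-Based Topography and Aging Trajectories of the Corpus
    Callosum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds connectivity-based parcellations of the corpus callosum
    from streamline tractograms and functional-network label volumes:
    per-subject connection-count and connection-probability maps,
    population-level probabilistic atlases with maximum-likelihood hard
    segmentation, split-half Dice reproducibility, probability-weighted
    extraction of diffusion-tensor indices (FA, MD, RD, AD) per callosal
    subregion, quadratic lifespan trajectory fitting with turning-point
    ages, and covariate-adjusted age-group comparisons. A synthetic phantom
    and cohort generator emulates the geometry and statistical structure of
    a midsagittal callosal cross-section crossed by homotopic bundles, so
    the whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
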