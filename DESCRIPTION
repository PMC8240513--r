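Package: groundcover
Title: Multi-Sensor Canopy Ground Cover Estimation and Reliability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates canopy ground cover (GC) for field-trial plots from
    three ground-based sensor streams: RGB images via greenness-index pixel
    thresholding, LiDAR point clouds via red-reflectance and canopy-height
    classification, and an active NDVI sensor via plot-mean aggregation.
    Includes a synthetic field-trial and sensor simulator (partial-replicate
    design with genotype, row and column effects; light-dependent RGB
    contrast; dew-dependent LiDAR reflectance; light- and dew-invariant
    NDVI), per-event random-effects variance decomposition with
    repeatability (broad-sense heritability) and BLUP genotype means, and
    the reliability analyses for diurnal sampling schedules: intraclass
    correlations across sampling times and phenotypic correlations between
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lme4,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
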