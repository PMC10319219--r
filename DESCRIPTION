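Package: floodscope
Title: Synergic SAR Change-Detection Flood Mapping and Cropland Damage
    Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps flood inundation from multi-temporal synthetic aperture
    radar (SAR) backscatter stacks by combining two change-detection
    indices - the change detection and thresholding (CDAT) difference and
    the normalized difference flood index (NDFI) - with an adaptive
    threshold (mean minus Kc standard deviations), a terrain/background/
    seasonal filter cascade, and a consistency (synergy) map.  Downstream
    tools characterize flood severity (multi-stage intensity, multi-year
    frequency, newly flooded area), validate maps against labeled samples
    and an optical NDVI/EVI/LSWI water rule, and score cropland damage
    from vegetation-index depressions (NDVI/EVI differences, modified
    vegetation condition index and its change) combined with flood
    intensity.  A synthetic scene generator with known ground truth makes
    the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
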