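Package: swardscan
Title: LiDAR Line-Scan Volumetrics for Forage Row-Plot Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes ground-based LiDAR line-scan height streams from
    single- and paired-row forage plots into a per-plot LiDAR Volume (LV)
    index: noise filtering, invalid-return handling, fixed-geometry plot
    segmentation with manual alignment offsets, per-plot ground estimation,
    height segmentation at a virtual cutting height, and cross-section
    integration. Includes an independent raster-surface integration path,
    a synthetic field simulator with analytic ground-truth volumes, and the
    downstream trait statistics used in forage breeding trials (percent
    dry matter, coefficient of variation, relative growth rate, yield
    regression with X-intercept, normalized covariance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
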