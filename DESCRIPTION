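Package: forage3d
Title: Horizontal and Vertical Foraging Indices for Diving Central-Place
    Foragers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives and relates indices of searching intensity in the
    horizontal plane and the vertical dimension from biologging records of
    diving central-place foragers such as harbour seals. Provides dive
    quality control and per-dive metrics (bottom time, standardized bottom
    time, time-at-depth, dive skewness), GPS track filtering,
    regularization and two-state movement classification, residence time,
    benthic/pelagic classification from distance to the sea bottom,
    trip-direction segmentation, detection of resting-while-diving through
    changepoint analysis of dive skewness, assembly of per-segment
    covariate tables, and resampled linear mixed-effects model selection
    relating the vertical index to each horizontal index. A synthetic-data
    generator produces tracks, dives, haul-outs and bathymetry with known
    ground truth so every stage is testable without deposited field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    mclust,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
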