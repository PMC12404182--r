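Package: thermalscape
Title: Heat Accumulation, Warming Velocity, and Vulnerability Tiers for
    Mountain Lake Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify climate vulnerability of mountain lake
    landscapes from monthly air-temperature series. Computes annual growing
    and killing degree days (GDD/KDD) with a monthly-mean day expansion and
    region-specific 90th-percentile killing thresholds, estimates a
    per-watershed velocity of thermal change from random-slope linear mixed
    models fitted by REML, classifies watersheds into cold, transitional
    and hot vulnerability tiers by one-dimensional k-means on mean
    historical GDD, and projects tier membership onto future period
    climatologies with a linear discriminant model. Includes a synthetic
    landscape and climate generator with known warming trends for
    end-to-end validation, tidy accessors for all fitted objects, ggplot2
    figures, and a reproducible pipeline driver that writes CSV artifacts
    and a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
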