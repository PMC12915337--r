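Package: aerodyn
Title: Seasonal Dynamics of Airborne Bacterial Abundance from Local
    Generation and Regional Dispersal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multi-year airborne bacterial abundance
    time series. Integrates qPCR 16S rRNA gene copy numbers with amplicon
    read compositions into absolute bacterial abundance, handles missing
    samples by seasonal averaging and interpolation, fits annual
    sine/cosine harmonics with phase-lag estimation, computes periodograms
    and classical decompositions, builds Spearman correlation networks
    with collinearity pruning and module detection, detects dust
    events and PM10 spikes and quantifies their before/during/after
    effects, converts desert-station AQI to PM10 and builds a smoothed
    dust-immigration index, and fits a maximum-likelihood structural
    equation model partitioning local generation from regional dispersal.
    A seeded synthetic-world generator reproduces the statistical
    structure of such monitoring campaigns so every stage can be exercised
    and validated against known truth.
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
    igraph,
    jsonlite,
    lubridate,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
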