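Package: sstshift
Title: Decomposing Sea-Surface-Temperature Change into Warming, Extremes and
    Variability to Explain Coastal Species Range Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for attributing local persistence or extirpation of coastal
    species to components of sea-surface-temperature (SST) change between two
    survey periods. Provides a calendar-aware data model for gridded daily SST
    series; a synthetic-data generator with controlled trend, seasonality,
    coloured noise and injectable discrete events; marine heatwave and cold-spell
    detection against a fixed-baseline day-of-year percentile climatology;
    temporal-variability statistics (unbounded seasonality, spectral noise
    colour, coefficient of variation, consecutive disparity index, skewness,
    thermal-threshold exceedance); anomaly table construction; correlation, VIF
    and AIC based variable screening; hierarchical partitioning of binomial
    goodness-of-fit with a randomization significance test and an iterative
    protocol for large variable sets; and non-metric multidimensional scaling
    with environmental vector fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
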