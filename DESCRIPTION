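Package: vmshapes
Title: Two-Step Cluster Analysis of Knee Valgus Moment Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies stance-phase knee valgus moment time series into
    waveform shape clusters and magnitude sub-clusters using a two-step
    hierarchical cluster analysis: curves windowed to early stance are reduced
    to the signs of their first differences, clustered with Ward.D2 linkage on
    Euclidean distances, and the number of clusters is chosen by the
    Hubert-Levin C-Index; within each shape, body-mass-normalized curves are
    sub-clustered by magnitude. Includes chi-square frequency analysis of the
    resulting labels across groups with per-cell contributions and a
    fixed-margin Monte-Carlo significance test, a synthetic stance-phase
    waveform generator for validation, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
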