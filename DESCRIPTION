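Package: habitwatch
Title: Behavioral Trend Detection and Habit Profiling from Home-Sensor Event Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analytics for ambient-assisted-living home monitoring of older
    adults. Converts timestamped event streams from simple home sensors (bed
    and chair occupancy, toilet presence, PIR motion, magnetic contacts) into
    rest intervals, daily visit counts and binary day traces; detects trends
    and anomalies in daily count behaviors with a rolling-window Poisson
    regression (baseline, abrupt, intermediate and linear-trend covariates,
    significance-based factor retention, central-interval labeling of
    unexplained days); and models presence habits with per-bin Bernoulli
    Sensor Profiles, including Wilson confidence intervals, Holm-adjusted
    binomial-proportion comparison of periods, agglomerative clustering of
    daily patterns under cosine distance with silhouette-based model
    selection, and a negative log-likelihood Novelty Score with an
    interquartile-range outlier threshold. A seeded simulator generates
    multi-day sensor streams with known ground truth (behavioral modes,
    trends, outlier days, transmission failures) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
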