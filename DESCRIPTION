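Package: infotrend
Title: Trend, Seasonality, and Environmental Association Analysis for
    Search-Interest Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An infodemiology pipeline for monthly relative search volume
    (RSV) series: B-spline trend estimation with a mean-instantaneous-
    derivative (MID) statistic and residual-bootstrap confidence intervals
    and p-values, a falsification-outcome contrast against a negative-control
    series, Kruskal-Wallis month-of-year seasonality testing, a Spearman
    correlation screen of interpolated and standardized environmental
    parameter panels, and dynamic-time-warping ranking of temporal alignment.
    Includes a synthetic-data generator with known ground truth so every
    stage is testable without external downloads.
License: MIT
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
    splines,
    stats,
    tibble,
    tidyr,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
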