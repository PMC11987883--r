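Package: farrowcast
Title: Continuous Prediction of Sow Farrowing Onset from Video-Derived Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for continuous prediction of farrowing onset in late-pregnancy
    sows from activity time series extracted by dense optical-flow estimation.
    Quantifies per-frame activity from optical-flow fields, builds sliding-window
    remaining-time datasets with subject-level splits, fits a hybrid
    convolution--LSTM regression model whose core is a position-aware
    time-weighted self-attention layer, and provides descriptive analyses
    (cross-sow activity correlation, seasonal-trend decomposition of the
    pre-farrowing activity rise, interval-wise prediction reports, and a
    return-on-investment calculator). A synthetic-cohort generator emulating
    pre-farrowing activity dynamics makes the full pipeline testable without
    farm video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
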