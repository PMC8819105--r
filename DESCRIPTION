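Package: abcscreen
Title: Dynamic Signal-Disruption Scoring for In Vitro Developmental
    Toxicity Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for live-cell luciferase reporter assays that
    monitor growth-factor signalling after chemical exposure. Raw plate-reader
    time courses are background-normalized, min-max scaled, and converted to
    vehicle-referenced log fold changes; smoothing splines with a fixed
    effective degrees of freedom summarise each condition, and the area between
    the vehicle and chemical spline curves (ABC) quantifies signalling
    disruption per concentration. Per-chemical sums of ABC feed a
    Jonckheere-Terpstra concentration-trend test, ROC analysis with
    closest-to-corner threshold selection, binary toxicant calls, and Hedge's g
    effect sizes. Includes a four-parameter log-logistic viability model with
    IC50 estimation for choosing exposure ranges, a synthetic plate generator
    for end-to-end validation, and a packaged reference table of 18 chemicals
    from the ECVAM validation panel.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
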