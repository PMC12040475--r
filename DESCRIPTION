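Package: woundrate
Title: Comparative Wound-Healing Kinetics with Penalized Random-Slope Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analyses of skin wound-closure kinetics
    across species. Converts longitudinal wound measurements (widths of
    circular experimental wounds, or areas of elliptic natural wounds via a
    day-one width-length relation and its positive-root quadratic inversion)
    into healing distances, fits Gaussian linear mixed models with
    group-specific slopes, per-individual random intercepts and slopes, and a
    boundary-avoiding log-determinant covariance penalty, extracts healing
    rates in mm per day with standard errors, and tests slope contrasts with
    Wald chi-square statistics. Includes a synthetic longitudinal data
    generator emulating multi-species wound-monitoring designs so the whole
    pipeline can be exercised and validated by parameter recovery.
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
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
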