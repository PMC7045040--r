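Package: memlag
Title: Pooled Seasonal Autoregressive Analysis of Daily Behavior Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pooled (panel) time-series analysis of daily count
    records such as cigarettes smoked per day: per-subject homoscedastic
    rescaling, seasonal autoregressive lag design with day-of-week dummy
    coding, constrained maximum-likelihood estimation of a mean plus
    covariance structure with SEM-style fit indices, pooled correlograms
    for panel data, Ljung-Box and Kolmogorov-Smirnov residual diagnostics,
    and a synthetic panel generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    lme4,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
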