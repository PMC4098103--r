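Package: lagresp
Title: Exposure-Lag-Response Associations with Distributed Lag Non-Linear Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modeling exposure-lag-response associations with
    distributed lag non-linear models (DLNMs) extended beyond time series
    data. Builds cross-basis design matrices from time-varying exposure
    histories by tensor-combining an exposure-response basis f(x) with a
    lag-response basis w(l), fits Cox proportional-hazards models with
    counting-process data and survival-adapted AIC/BIC model selection, and
    predicts lag-response curves, exposure-response curves, bidimensional
    risk surfaces and overall cumulative effects with delta-method confidence
    intervals. Includes a permutational simulation engine for generating
    time-to-event data conditional on known exposure-lag-response surfaces,
    and a study driver that evaluates bias, coverage, root mean square error
    and model-selection behavior of the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    splines,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
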