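Package: bloodcast
Title: Time-Series Forecasting of Red Blood Cell Demand
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-stage forecasting of red blood cell (RBC) issues for blood
    services: smoothing of daily issue counts into nonoverlapping weekly and
    4-week series, windowed polynomial detrending, and four linear prediction
    methods (minimum mean squared error coefficients and residual-based
    weighted averages) for horizons of one to six 4-week periods ahead.
    Includes rolling-origin evaluation with a percentage-error figure of
    merit, parameter grid search over window size, prediction order and
    polynomial order, a synthetic daily-demand simulator with weekday and
    annual structure, CSV input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
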