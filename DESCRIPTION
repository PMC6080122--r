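Package: cgmperf
Title: Measurement-Performance Evaluation of Continuous Glucose Monitoring Systems
Version: 0.1.0
Authors@R:
    person("CGM", "Performance Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate the point accuracy and precision of continuous
    (tissue) glucose monitoring (CGM) systems against blood glucose reference
    measurements. Implements the field-standard pairing rules (last observation
    carried forward within 5 min, scan matching within +/-3 min, minutely
    linear interpolation), deviation statistics split at 100 mg/dL (MAD below,
    MARD above), threshold-exceedance tables, sensor-to-sensor precision
    (PAD/PARD), consensus (Parkes) error grid classification for type 1
    diabetes, and multi-level aggregation across sensors, application sites and
    participants. A synthetic-study generator reproduces the structure of a
    14-day, 20-participant head-to-head wear study (clinic visits with induced
    glucose excursions, home-use phases, duplicate meter measurements) so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
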