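Package: actdays
Title: Reliability-Based Planning of Wrist Accelerometer Monitoring Days
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Processes raw wrist-worn tri-axial accelerometer recordings into
    ENMO-based daily physical-activity constructs (overall activity in mg,
    light-activity minutes, bouted moderate-to-vigorous activity minutes),
    screens them with autocalibration, abnormal-value and non-wear detection,
    and estimates how many monitoring days are needed for a reliable estimate
    of habitual physical activity: the single-day intraclass correlation of
    each construct is stepped up with the Spearman-Brown prophecy and inverted
    at a target reliability.  A two-tier synthetic cohort generator with known
    variance components makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
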