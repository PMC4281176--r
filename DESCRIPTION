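Package: spiroqc
Title: Automatic Quality Assessment of Forced Spirometry Maneuvers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic quality grading of forced-spirometry maneuvers from
    their curve morphology. Computes the classical spirometric indices (FVC,
    FEV1, PEF, back-extrapolated volume, end-of-test volume, forced
    expiratory time), segments each flow-volume curve into five analysis
    zones, evaluates a battery of shape criteria (derivative regularity,
    peak morphology, end-of-test plateau, single-peak checks) alongside the
    traditional ATS/ERS acceptability rules, and maps the outcomes to a
    three-level quality grade: reject, acceptable, or needs expert review.
    Includes a synthetic-maneuver generator with injectable defects (delayed
    start, cough, bimodal or flat peak, early termination, end-of-test
    oscillation, irregular ascent or descent) so the whole battery can be
    exercised and validated without patient data, plus delimited-text
    readers/writers, a flat-file threshold configuration, session-level
    repeatability checks, and sensitivity/specificity scoring against
    expert labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
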