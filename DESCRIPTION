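Package: daylongr
Title: Analysis of Daylong Child-Centered Audio Recording Diarization Output
Version: 0.1.0
Authors@R:
    person("daylongr", "developers", email = "daylongr@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing speaker-diarized segment tables from daylong
    child-centered audio recordings (LENA-style output): clip filtering,
    hourly-normalized quantity and consistency metrics of caregiver speech
    input and child vocal output, conversational-turn detection under a 5
    second contingency window, cross-sectional age-slope and mixed-effects
    group models for matched cochlear-implant / typical-hearing cohorts, and
    a calibrated synthetic-cohort generator for end-to-end parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    optparse,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
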