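Package: alarmprofile
Title: Timeliness-Binned Performance Characterization of Early-Warning
    Alarm Systems
Version: 0.1.0
Authors@R:
    person("Analysis", "Tools", email = "tools@example.org", role = c("aut", "cre"))
Description: Characterizes early-warning alarm systems operating on
    continuously monitored vital signs. Every warning raised on a cohort of
    records is categorized by its lead time relative to a critical event into
    five bins (False, Early, On Time, Late, Missed) and summarized as two
    normalized profiles: warning proportions (per-warning unit of analysis)
    and warnings per record (per-record unit of analysis), alongside
    traditional per-record metrics (positive predictive value, sensitivity,
    false positive rate). Includes a normalized Shock Index warning indicator
    (heart rate over systolic blood pressure mapped through a Gaussian CDF
    fitted to population baseline data), threshold (RESPONSIVE) and latching
    (STAY-ON) alarm strategies, CSV ingestion of vital-sign records and
    pre-extracted fiducial tables, a synthetic vital-sign cohort generator
    emulating hemorrhage-induced hypotension, chart rendering, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
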