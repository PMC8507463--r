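Package: obsdex
Title: Headless Engine for DICOM Observer-Performance Studies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable engine for administering medical-image observer
    performance studies (ROC, FROC and alternative-forced-choice designs)
    over a folder-based DICOM case database. Provides a plain-text study
    property file with validation, per-observer deterministic randomization
    of case order and of series-to-canvas placement (the AFC enabler), a
    multi-monitor multi-canvas display model with windowing, scrolling and
    temporary layout changes, physical measurements (distance in mm,
    circular and freeform ROI area in mm2 with mean pixel value), a
    forward-only review session state machine with show/edit modes, an
    append-only two-delimiter study log with lossless parser and tidy CSV
    export, and a synthetic DICOM fixture generator so studies run with no
    external data. Includes a command-line interface for fully headless,
    scripted sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    utils
Suggests:
    mgcv,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
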