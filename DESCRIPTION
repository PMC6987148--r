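Package: fovarea
Title: Foveal-Vision Analysis of Free Visual Exploration Eye-Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of video-oculography fixation data from free visual
    exploration (FVE) paradigms, aimed at visuospatial attention research and
    hemispatial neglect assessment. Computes binary foveal-coverage rasters and
    the resulting visual exploration area per screen half (picture-wise and
    cumulative), classifies fixations into single versus overlapping and
    overlapping fixations into capture versus re-capture, and provides the four
    conventional FVE neglect indicators (mean horizontal gaze position,
    leftmost fixation, per-half fixation counts and cumulative durations)
    together with the group-comparison statistics (Welch t-tests, balanced
    split-plot mixed ANOVAs, Bonferroni post hocs, Cohen's r and partial
    eta-squared). Includes a seeded synthetic-cohort generator emulating
    control-like and neglect-like exploration behaviour so the full pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
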