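Package: esmviz
Title: Visual Feedback for Single-Subject Experience-Sampling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for turning raw single-subject experience-sampling (ESM)
    time series into descriptive visual feedback: a typed questionnaire and
    dataset model with validation, CSV import/export in wide and long
    dialects, a seeded simulator of a year-long three-prompts-a-day study
    with relapse episodes and compliance gaps, descriptive statistics
    (Tukey boxplot summaries, tricube local regression smoothing,
    missingness tables, polarity composites, episode flagging), circle-glyph
    figures with week grids and an all-responses poster, per-week movie
    frames encoded to animated GIF, a self-contained interactive HTML
    report, and a command-line interface wiring the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glue,
    grDevices,
    grid,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
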