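Package: numstim
Title: Controlled Numerosity Stimulus Arrays for Non-Symbolic Number Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates arrays of shaped elements (dot patterns and related
    stimuli) whose numerosity and continuous physical variables -- mean
    inter-distance, convex hull, density, element size, total perimeter and
    total area -- are controlled independently or in combination to a stated
    percent tolerance. Provides seeded rejection sampling of point
    configurations, radius policies (equal, Gaussian with pinned extremes,
    free), magnitude fitting for total area or perimeter, homothetic convex
    hull refinement, exact-scale PNG rendering with single or paired layouts,
    metadata tables, and trial sequencing for habituation/dishabituation and
    simultaneous dual-choice paradigms.
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
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
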