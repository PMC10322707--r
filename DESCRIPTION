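Package: cephalosleep
Title: Quantitative Analysis of Two-Stage Sleep in Octopus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying the behavioural, electrophysiological and
    skin-patterning correlates of two-stage (active/quiet) sleep in octopus.
    Detects colour flashes and active-sleep bouts from video-derived skin
    brightness traces, fits circadian and temperature models of bout timing,
    quantifies arousal reactions and breathing from movement traces,
    preprocesses multi-channel local field potential recordings, measures
    state-dependent band intensities, spectrograms and multitaper spectra,
    detects spindle-like quiet-sleep oscillatory events and aggregates them
    over brain regions, computes trajectory statistics (dynamic time warping,
    parallel analysis, silhouette overlap) on skin-pattern feature
    trajectories, and aligns mantle images by moving-least-squares warping.
    Includes a synthetic-data generator emulating the statistical structure of
    all recording modalities, with ground truth for parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    cluster,
    stats,
    withr
Suggests: testthat (>= 3.0.0), jsonlite, readr
Config/testthat/edition: 3
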