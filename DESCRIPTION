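Package: ecogsep
Title: Separability of Global Cortical Activity Distributions in Multichannel ECoG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects stimulus-evoked global shifts in the distribution of
    cortical activity across multichannel electrocorticogram (ECoG) recordings.
    The cross-channel signal at each time step is embedded with principal
    component analysis, and evoked versus spontaneous samples are compared with
    a repeated, cross-validated k-nearest-neighbour separability statistic
    evaluated against a label-shuffle permutation null. Includes stimulus
    artifact interpolation, per-channel z-scoring, Savitzky-Golay smoothing for
    visualisation, channel-subset ablation variants, per-component knockout and
    incremental sensitivity analyses, condition summaries with rank-sum
    comparisons, and a seeded synthetic ECoG session generator emulating an
    alternating spontaneous/stimulation protocol under ketamine-like slow
    oscillations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    class,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
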