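Package: betakin
Title: Imaging-Based Counting and Proliferation Kinetics of Cultured Beta Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for following living beta-cell numbers in culture by
    whole-well fluorescence imaging: a stochastic birth-death simulator of a
    cultured beta-cell population with glucose-dependent recruitment into the
    cell cycle, a post-mitotic refractory period, death and dead-cell
    disintegration, and dual thymidine-analog (EdU/BrdU) labeling windows; a
    synthetic multichannel well-image renderer with per-cell ground truth;
    nuclear segmentation with annular-ring cytoplasm measurement and the
    corrected living-beta-cell count; and the derived cell-kinetics statistics
    including the stochastic (independence) re-entry prediction, percent-of-day-1
    normalization, per-cell insulin normalization and summary-statistic t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
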