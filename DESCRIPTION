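Package: ecogreach
Title: Linear Decoding of 3-D Reach Kinematics from ECoG Band-Power Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline decoding of the first principal component of
    three-dimensional reaching movements from electrocorticographic (ECoG)
    recordings. Implements the full analysis chain: common average
    re-referencing, a zero-phase Hamming-window FIR filter bank over seven
    canonical frequency bands plus the local motor potential (LMP),
    smoothed log band-power features at the kinematic sampling rate,
    per-fold kinematic normalization and principal component analysis,
    lagged-correlation feature selection, ordinary-least-squares decoding
    under fivefold cross-validation, and chance calibration via feature
    shuffling with Wilcoxon, two-way ANOVA (Dunn-Sidak) and Kruskal-Wallis
    saturation analyses. A synthetic-session generator with known
    channel/band/lag encoding provides a fully verifiable test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    signal,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
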