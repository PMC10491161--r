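Package: dusktools
Title: Sleep, Activity and Voltage-Imaging Analysis Around Dusk for
    Drosophila Monitor Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying crepuscular behavior of Drosophila from
    Trikinetics Activity Monitor (DAM) recordings and for analysing in vivo
    fluorescence voltage-imaging traces of clock neurons. Implements the
    5-minute inactivity rule for sleep scoring, sleep bout extraction,
    post-dusk sleep-onset latency, windowed sleep amounts and changes,
    evening anticipation slope and evening peak phase from binned activity,
    a spike-detection pipeline for negative-going voltage-indicator
    transients (photobleach detrending, zero-phase Butterworth filtering,
    band-pass moving-baseline estimation, threshold local-minima spike
    calling), a statistics layer (one-way ANOVA with Bonferroni planned
    comparisons, Kruskal-Wallis with Dunn's post hoc, normality gating,
    experimental-versus-both-controls verdicts), and a fully seeded
    synthetic-data generator that emits DAM-format behavior and
    voltage-indicator-like traces with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
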