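Package: sleseg
Title: Segmentation and Analysis of Seizure-Like Events in Local Field
    Potential Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying epileptiform activity in single-channel
    local field potential (LFP) recordings from acute brain slices under
    disinhibiting conditions. Provides a synthetic LFP generator with known
    ground-truth seizure-like events (SLEs), a small trainable
    dilated-convolution network for per-sample SLE segmentation, rule-based
    post-processing of predicted labels (short-event removal, gap merging,
    endpoint snapping to the final extremum), spike detection and SLE
    metrics (fraction, duration, rate, intra-event spike frequency),
    periodogram-based power spectral density analysis with 0.2-Hz binning
    and bootstrap confidence bands, and nonparametric group statistics
    (Kruskal-Wallis, Dunn's post hoc with Holm-Bonferroni correction,
    Fisher exact test).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    IRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
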