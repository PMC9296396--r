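Package: dyadsync
Title: Interpersonal Movement Synchrony from Dyadic Video by Motion Energy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies nonverbal interpersonal synchrony between two
    interacting people from video or pre-extracted movement time series.
    Motion energy is obtained by thresholded grayscale frame differencing
    within fixed head and upper-body regions of interest; synchrony is the
    mean absolute Fisher-Z-transformed windowed lagged cross-correlation of
    the two interactants' motion-energy series. A surrogate re-pairing null
    (pseudosynchrony) and the accompanying two-sample statistical battery
    (Shapiro-Wilk gating, pooled t, Mann-Whitney U, Cohen's d, group-mean
    imputation, within-group correlations) are included, together with a
    synthetic-data generator producing coupled, bursty, autocorrelated
    dyadic series and cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
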