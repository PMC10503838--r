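Package: photogam
Title: Photoperiod Locomotor Trajectory Analysis with Penalized-Spline
    Additive Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multiwell larval locomotor assays under
    programmable light regimens: photoperiod schedule construction, per-second
    distance traces and their rolling-sum response, a zero-inflated Gamma
    trace simulator, an identity-link additive model engine with per-group
    penalized spline smooths of time and assay-level random intercepts
    (REML or GCV smoothness selection), per-second estimated marginal means
    with Tukey-adjusted pairwise contrasts, proportion-of-significance
    summaries per photo period, and Yates-corrected two-proportion tests
    between assay regimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    splines,
    stats,
    utils,
    yaml
Suggests:
    emmeans,
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
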