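Package: cogload
Title: Autonomic Markers of Cognitive Load from Electrodermal Activity and
    Heart Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction of autonomic nervous system markers of cognitive load
    from electrodermal activity (EDA) and heart-rate variability (HRV).
    Implements three phasic-EDA indices (a convex-optimization tonic/phasic
    decomposition, variable-frequency complex demodulation, and level-3
    wavelet-packet band energies), classical and time-frequency HRV indices,
    and the downstream inference chain: assumption-guarded repeated-measures
    condition comparisons, mixed-effects prediction of perceived workload with
    collinearity screening and stepwise backward selection, and k-means
    autonomic profiling.  A synthetic-session generator with known ground
    truth (Poisson skin-conductance responses, integral pulse frequency
    modulated beat series, random-intercept self-reports) makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    splines,
    Matrix,
    lme4,
    cluster,
    jsonlite,
    tibble
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
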