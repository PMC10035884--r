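Package: nftheta
Title: Simulation and Analysis of Frontal-Midline Theta Neurofeedback Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A config-driven simulation and analysis toolkit for closed-loop
    frontal-midline theta (4-7 Hz) neurofeedback protocols paired with a
    Go/No-Go shooting task. Provides synthetic-subject generators (1/f
    background EEG, goal-responsive narrowband theta, artifact transients, a
    psychometric virtual shooter), a streaming Welch-style theta-power
    feedback engine with artifact gating and adaptive thresholds, protocol
    and target-schedule builders, offline spectral analysis with
    multi-criterion epoch rejection and retention accounting, and a
    multilevel-model stage (REML random-intercept/slope models, ICC, design
    effect, fixed-effects pseudo R-squared, simple slopes, responder
    classification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
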