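Package: spikephase
Title: Spike-History and LFP-Phase Models of Neuronal Spike Timing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Point-process logistic models that test whether, and when,
    neuronal spike timing is constrained by refractoriness and by the phase
    of local field potential (LFP) rhythms. Provides short- and long-history
    spike GLMs, a cross-validated circular kernel density estimator of
    spike-phase coupling with a Bayes posterior over spiking, combined
    phase-plus-history models fit on log-odds, held-out log-loss model
    comparison across train-test splits with split-level and time-windowed
    t-tests, within-cycle phase-permutation controls, the Rayleigh test,
    Butterworth/Hilbert phase extraction, and a simulator of refractory and
    rhythmically modulated spike trains for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    signal,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
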