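Package: phasicpupil
Title: Pupillometry and Oscillatory Power Analysis for Phasic Auricular
    Vagus Nerve Stimulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for phasic, event-related transcutaneous
    auricular vagus nerve stimulation (taVNS) experiments combining
    pupillometry and MEG-like electrophysiology.  Provides a seeded
    synthetic-data generator for two tasks (an emotional Stroop task and a
    passive pupil light reflex task), pupil-trace cleaning by a two-pass
    dilation-speed / median-absolute-deviation procedure, extraction of
    pupil light reflex kinematics (onset latency, constriction amplitude
    and velocities), stimulation-artifact removal by pulse-locked blanking
    with autoregressive gap filling, Hanning-tapered FFT spectra and Morlet
    time-frequency power with decibel baselining, mixed-effects models of
    trial-level behavior with likelihood-ratio tests and nested-model
    interaction resolution, cluster-based permutation testing over
    per-point statistics with paired Cohen's d cluster effect sizes, and
    cross-task prediction of stimulation-specific deltas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
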