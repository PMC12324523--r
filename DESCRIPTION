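Package: striatr
Title: Signal Processing and Behavioral Metrics for Striatal Dopamine Studies
Version: 0.1.0
Authors@R: person("striatr", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for quantifying striatal dopamine signals and
    the behaviors they accompany. Converts dual-channel fiber-photometry
    recordings (465 nm dopamine-sensor signal plus 405 nm isosbestic
    reference) into z-scored dFF traces via isosbestic least-squares
    correction, computes peri-event trial matrices with inter-trial-interval
    baselines, AUC and peak metrics, and detects spontaneous dopamine
    transients by peak prominence. Quantifies evoked dopamine transients from
    fast-scan cyclic voltammetry sweeps (peak amplitude Imax and clearance
    time constant Tau1). Computes nonparametric circadian statistics
    (interdaily stability, intradaily variability) and light/dark phase
    summaries from epoch-binned piezo activity, and behavioral metrics from
    operant (continuous-reinforcement and fixed-interval) and gustometer lick
    session logs. Every analysis stage is exercised against synthetic data
    generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
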