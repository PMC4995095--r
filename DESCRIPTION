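Package: twitchgate
Title: State-Dependent Sensory Gating Analysis for Neonatal
    Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for sleep-wake electrophysiology in
    neonatal rodents: EMG-based scoring of wake and active-sleep bouts,
    detection of myoclonic twitches and wake movements by amplitude and
    duration criteria, RMS-threshold detection of cortical spindle
    bursts, perievent spike correlations and waveform averages with
    interval-jitter surrogates and simultaneous acceptance bands, and
    pre/post-infusion delta-firing-rate analysis with quiescence
    baseline subtraction.  Includes a synthetic-session generator with
    full ground truth for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
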