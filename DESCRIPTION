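Package: gaintrack
Title: Neural Mass Modelling and Unscented Kalman Tracking of Inhibitory
    Synaptic Gain
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Forward simulation of the Jansen-Rit neural mass model, a
    slow-fast extension in which the inhibitory synaptic gain evolves on an
    infraslow time scale and produces transitions into and out of seizure-like
    activity with DC baseline shifts, and a continuous-discrete unscented
    Kalman filter that tracks the inhibitory gain from a single observed
    trace.  Includes signal-conditioning utilities (zero-phase Butterworth
    high-pass at a clinical 0.3 Hz corner, rescaling, decimation), a
    synthetic-recording generator that emulates DC-coupled seizure
    electrophysiology, and an experiment pipeline comparing gain tracks
    recovered from wide-bandwidth versus high-pass-filtered versions of the
    same trace.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    yaml,
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
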