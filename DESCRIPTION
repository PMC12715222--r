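Package: thetagamma
Title: Prefrontal LFP Oscillations and Fear-Extinction Behavior Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking medial prefrontal cortex local field
    potential (LFP) oscillations to fear-extinction behavior in mice.
    Implements the LFP conditioning chain (Butterworth band-pass, narrow IIR
    notch, integer decimation), Welch power spectral density estimation with
    whole-spectrum and baseline normalization, theta/low-gamma/high-gamma
    relative band power, Hilbert-based theta-phase to gamma-amplitude coupling
    (Tort modulation index) with a tone/ITI coupling ratio, trial and stage
    segmentation of 40-tone extinction sessions, freezing and open-field
    behavior scoring, a Shapiro-Wilk-gated two-group test harness with
    factorial contrasts, and a synthetic-cohort generator with ground-truth
    bookkeeping for validating every stage against known effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
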