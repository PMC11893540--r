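Package: gammaflick
Title: Analysis of 40 Hz Visual Flicker Entrainment in Sleep EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying steady-state visually evoked responses to 40 Hz
    flicker delivered during sleep. Provides a synthetic polysomnography
    generator (1/f background EEG with stage-specific oscillations, a
    closed-loop stimulation schedule, evoked 40 Hz responses, artifacts), EDF
    and CSV input/output, the preprocessing chain up to labelled 30-second
    epochs, epoch-level Hamming-window spectra with 40 Hz power (PSD40) and a
    neighbour-band signal-to-noise ratio, stimulus-locked 25-millisecond SSVEP
    averaging with a shuffled-segment permutation SNR and an LED-artifact
    interpolation control, sleep macrostructure metrics, and an
    assumption-gated battery of paired and multilevel hypothesis tests with
    effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
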