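Package: pulsecall
Title: Pulse-Train Modelling and Harmonic Analysis of Blue Whale B Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Synthesis and analysis toolkit for the pulsed-air model of
    northeastern Pacific blue whale B calls. Generates call waveforms by
    repeating a closed-form biphasic pressure wavelet at a constant or
    time-varying inter-pulse interval, implements the competing
    variable-phase sinusoid (resonance-style) model, reads harmonic
    structure (fundamental and overtones) off power spectra and
    spectrograms, fits both models to mono hydrophone recordings by
    normalized cross-correlation over a forward-modelling grid, and
    simulates synthetic hydrophone scenes (multipath echoes plus
    band-limited ambient noise) with full ground truth for parameter
    recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
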