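Package: sleeparousal
Title: Sleep, Arousal and Fan-Shaped-Body Electrophysiology Analysis for Drosophila
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Drosophila sleep and behavioral-arousal
    experiments in which locomotor activity is tracked while periodic
    mechanical vibration stimuli probe responsiveness, together with
    intracellular membrane-potential and local-field-potential analyses of
    optogenetically activated dorsal fan-shaped-body neurons. Implements
    5-minute sleep-bout detection, stimulus-locked response curves with a
    single-inactivation exponential fit and analytic peak, responder calls and
    sleep-intensity measures by prior-immobility bin, day/night correlations
    between sleep and responsiveness, light-evoked membrane-potential changes
    and composite pulse averages, spike and burst classification, Morlet
    wavelet spectrograms with baseline-zeroed 1-15 Hz power ratios, and
    event-related-potential peak amplitudes. A synthetic-data module generates
    behavioral cohorts and electrophysiological traces with known planted
    parameters so every analysis stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    signal,
    ggplot2,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
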