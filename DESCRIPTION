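Package: thermocode
Title: Psychophysics and Afferent Coding of Forepaw Warm Perception
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing go/no-go thermal-detection behaviour and
    thermosensitive C-fiber afferent recordings, together with a
    dual-channel population model of warm coding. Includes construction of
    ramp-hold-ramp thermal stimulus waveforms, synthetic behavioural
    sessions from a parametric observer, inhomogeneous-Poisson simulation
    of warm-excited and cool-driven (warm-inhibited) C-fiber spike trains
    with genotype lesion presets, signal-detection analysis (boundary
    corrected d-prime, lick latencies, peri-stimulus time histograms,
    perceptual thresholds), afferent unit classification by conduction
    velocity and modality, and an ideal-observer decoder that pools
    warm-evoked excitation and suppression of ongoing activity across a
    simulated afferent population.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
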