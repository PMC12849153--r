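Package: ecgsonify
Title: ST-Elevation Sonification of 12-Lead ECG Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-based parameter-mapping sonification engine for
    continuous auditory monitoring of the ST segment in 12-lead ECG.
    Per-beat, per-lead ST-segment deviation is estimated against the PR
    baseline, classified into five clinical levels (strong/moderate
    suppression, isoelectric, moderate/strong elevation), and mapped to
    short pitched tones whose pitch, duration, brightness and level encode
    the deviation, anchored to the familiar QRS beep. Grouped lead scans
    play the six limb leads in Cabrera order and the six precordial leads
    as two six-tone messages on a fixed beat schedule. Includes a
    synthetic 12-lead ECG generator emulating anterior and inferior STEMI
    scenarios with graded severity, an offline additive-synthesis audio
    renderer with WAV output, and readers/writers for delimited and
    waveform-record ECG formats, so the whole chain is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
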