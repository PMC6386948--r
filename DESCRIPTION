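Package: piezoid
Title: Person Identification from Sheet-Type Piezoelectric Sensor Cardiac Vibration Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for identifying which person is resting on a sheet-type
    piezoelectric vibration sensor from the frequency spectrum of the
    cardiac-derived (ballistocardiographic) signal. The pipeline selects a
    stable 10-second analysis segment, band-limits it to the 0.6-15 Hz
    cardiac vibration band, computes a unit-integral normalized power
    spectrum, and extracts two spectral-shape discriminants: the number of
    peak shapes at the 1/2 and 1/4 power standards and the sharpness of
    those peaks (reciprocal of the summed above-threshold peak areas per
    peak). Enrolled subjects are matched by nearest-centroid search in the
    (peak count, regression residual) plane. A seeded synthetic-signal
    simulator generates labeled cohorts of heartbeat harmonic-comb
    recordings with bounded beat-interval jitter, amplitude-modulated
    harmonics, respiration, noise and movement artifacts for evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
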