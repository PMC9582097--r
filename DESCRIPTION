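Package: dqemam
Title: Detective Quantum Efficiency Measurement for Digital Mammography Detectors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Implements the IEC 62220-1-2 measurement chain for the detective
    quantum efficiency (DQE) of digital mammography detectors: signal transfer
    property (STP) linearization of raw DICOM images to photon-fluence units,
    slanted-edge presampling modulation transfer function (MTF), overlapping-ROI
    noise power spectrum (NPS/NNPS) by periodogram averaging with selectable
    trend removal, frequency-dependent DQE with GUM-style uncertainty
    propagation, and a synthetic detector model that generates flat-field,
    slanted-edge and calibration images with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
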