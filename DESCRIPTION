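Package: lockinamp
Title: Digital Lock-In Amplification for Fluorescence Biosensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Streaming dual-phase digital lock-in demodulation for
    square-wave-modulated fluorescence signals, together with a synthetic
    photodetector front-end simulator (analogue conditioning, mains and
    ambient interference, white noise, 12-bit quantisation) and the
    calibration analysis used to characterise fluorimetric assays:
    background subtraction, through-origin sensitivity fits, 2-sigma
    detection limits, linear range and dynamic range.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
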