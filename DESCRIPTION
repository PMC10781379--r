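Package: feverwatch
Title: Non-Contact Fever and Cough Monitoring with Self-Calibrating
    Thermopile Imaging and Spectrogram-Based Cough Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully simulated point-of-care monitoring pipeline combining a
    self-calibrating non-contact temperature measurement method with a
    spectrogram-based cough classifier and JSON event telemetry. A 24x32
    thermopile imager is modelled viewing two PID-heated Peltier reference
    patches; the two references anchor a per-measurement two-point (affine)
    calibration that cancels sensor gain and offset error, and the patient is
    located as the hottest non-reference pixel with 3x3 neighbourhood
    averaging. The audio path standardizes clips to 16 kHz mono, applies a
    pre-normalization silence gate, computes 129-bin magnitude spectrograms,
    and classifies them with a small seeded convolutional network trained on a
    bundled synthetic five-class sound generator (cough, other, music,
    conversation, ambient). Detections are emitted as JSON packets over TCP
    with UDP server discovery; a loopback mock server supports end-to-end
    interoperability tests without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: POSIX sockets (Linux)
OS_type: unix
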