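Package: ppghrv
Title: Heartbeat Interval Detection and HRV Estimation from
    Photoplethysmography via Wavelet Ridge Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Offline detection of heartbeat-to-heartbeat (RR) intervals in
    photoplethysmography (PPG) signals, including smartphone-camera
    recordings.  Peaks are located as top points of ridge lines in the
    continuous wavelet transform scalogram (Mexican hat mother wavelet),
    guided by a heart-rate frequency curve tracked on the short-time
    Fourier transform spectrogram.  Each detected interval is scored by
    signal self-similarity and ridge-line shape stability; corrupted
    signal parts are discarded via an adaptive quality threshold and
    interval-length outlier rules.  Reports SDNN, RMSSD and the
    per-signal discarded ratio, and ships a deterministic synthetic PPG
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    zoo,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
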