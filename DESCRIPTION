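Package: webeat
Title: Heartbeat Detection in ECG and PPG via Wavelet Enhancement and Upper Envelopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects heartbeats in single-channel electrocardiogram (ECG) and
    photoplethysmogram (PPG) recordings. QRS complexes are enhanced with a
    maximal-overlap discrete wavelet transform (Symlet-4) restricted to the
    5-20 Hz band, and beats are localised by comparing candidate peaks against
    the mean of two upper envelopes built by piecewise cubic Hermite
    interpolation, which acts as an amplitude-adaptive threshold. Includes an
    online (sliding-buffer) variant of the detector, PPG preprocessing via the
    first derivative and a 30 Hz low-pass filter, beat-by-beat evaluation
    metrics (true positive rate, positive predictive value, accuracy), readers
    and writers for plain-text signals, minimal WFDB record support, and a
    synthetic ECG/PPG generator with exact beat ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
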