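Package: pcgdenoise
Title: Wavelet Denoising and Noise-Level Evaluation for Phonocardiograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for low-noise heart-sound (phonocardiogram) processing:
    a digital emulation of an analog front end (4th-order Butterworth
    low-pass followed by a twin-T power-line notch), wavelet shrinkage
    denoising (level-4 'db10' decomposition, hard elimination of the
    500-1000 Hz band, soft minimax thresholding of the remaining bands),
    and a frame-spectral estimated-noise-ratio (ENR) statistic for
    comparing the noise level of two recordings. Includes a seeded
    synthetic phonocardiogram and noise generator so the whole chain is
    testable without recorded data, WAV input/output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
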