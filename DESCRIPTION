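Package: tfdenoise
Title: Time-Frequency Denoising of Single-Trial Event-Related Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-channel denoising of event-related EEG trials in the
    time-frequency domain. A trial is mapped to a complex spectrogram by a
    short-time Fourier transform, the magnitude image is decomposed by
    bidimensional empirical mode decomposition into intrinsic mode images plus
    a residue, each component image is smoothed by non-local means filtering,
    and the filtered magnitude is recombined with the original phase and
    inverted back to the time domain. Comparison denoisers (EEMD-ICA,
    EEMD-CCA, wavelet soft thresholding), a seeded synthetic ERP generator
    with structured noise, and a correlation-to-reference benchmarking
    harness are included, together with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
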