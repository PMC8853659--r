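Package: pupilflux
Title: Frequency-Resolved Coupling of Pupil-Linked Arousal and Cortical Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for resting-state coupling between pupil-linked
    arousal and multichannel neurophysiological recordings. Provides pupil
    preprocessing (blink interpolation, canonical event-response removal,
    zero-phase 0.005-2 Hz band-pass, derivative), Morlet wavelet power
    envelopes on a 25-frequency log-spaced grid (2-128 Hz), Gaussian-copula
    mutual information with time-shift surrogate standardization, lagged
    cross-correlation of amplitude envelopes with anterior-posterior spatial
    binning, forward-shifted Spearman correlation maps, segment-wise Welch
    spectra with aperiodic (1/f) spectral parameterization, binned quadratic
    (inverted-U) pupil-power models, microsaccade detection with event-locked
    spectral power, group-level t-tests with Benjamini-Hochberg FDR control,
    and a synthetic-data generator with ground-truth coupling structure for
    end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
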