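# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

# short artifact-free pupil recording
quiet_pupil <- function(duration = 90, fs = 400, seed = 42) {
  generate_pupil(duration, fs, blink_rate_hz = 0, saccade_rate_hz = 0,
                 seed = seed)
}

# one compact coupled subject (single channel, linear coupling at 11.3 Hz)
small_linear_subject <- function(duration = 120, seed = 7, gain = 0.5,
                                 lag_s = -0.93, n_channels = 1) {
  cp <- data.frame(group = "all", center_hz = 11.3137, gain = gain,
                   quad = 0, lag_s = lag_s)
  synth_subject(ground_truth(cp, seed = seed), duration_s = duration,
                fs_hz = 400, n_channels = n_channels, seed = seed)
}

# synthetic power spectrum: power law plus optional Gaussian peaks (log10)
powerlaw_psd <- function(f, chi, offset = 1, peaks = NULL) {
  y <- offset - chi * log10(f)
  if (!is.null(peaks))
    for (i in seq_len(nrow(peaks)))
      y <- y + peaks$height[i] *
        exp(-(f - peaks$center[i])^2 / (2 * (peaks$width[i] / 2)^2))
  10^y
}

expect_no_nan <- function(x) expect_true(all(is.finite(x)))
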