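# Pupil preprocessing: area conversion, blink interpolation, canonical
# event-response removal, band-pass + derivative, Hippus spectrum.

test_that("area to diameter is the closed-form conversion", {
  expect_equal(area_to_diameter(pi), 2)
  expect_equal(area_to_diameter(0), 0)
  expect_equal(area_to_diameter(4 * pi), 4)
  expect_true(is.nan(area_to_diameter(NaN)))
  expect_error(area_to_diameter(-1), "negative")
})

test_that("blink gaps in linear data are restored exactly", {
  fs <- 400
  x <- seq(0, 10, length.out = 40 * fs)      # linear ramp
  x_gap <- x
  x_gap[2000:2080] <- NaN                    # ~200 ms gap
  res <- detect_and_interpolate_blinks(x_gap, fs)
  expect_equal(res$x, x, tolerance = 1e-9)
  expect_true(all(res$interp_mask[2000:2080]))

  # clean input passes through untouched
  set.seed(1)
  clean <- 5 + cumsum(rnorm(4000)) / 1000
  res2 <- detect_and_interpolate_blinks(clean, fs)
  expect_identical(res2$x, clean)
  expect_false(any(res2$interp_mask))

  expect_error(detect_and_interpolate_blinks(rep(NaN, 100), fs), "entirely")
})

test_that("injected blinks are all marked and fraction matches truth", {
  p <- generate_pupil(120, 400, seed = 3)
  res <- detect_and_interpolate_blinks(p$diameter, p$fs)
  # every true gap region intersects the mask
  runs <- rle(res$interp_mask)
  n_regions <- sum(runs$values)
  expect_gte(n_regions, length(p$blink_onsets) * 0.9)
  true_frac <- mean(!is.finite(p$diameter))
  # mask covers gaps plus the configured padding margin (0.15 s per side)
  pad_extra <- length(p$blink_onsets) * 2 * 0.15 / 120
  expect_lt(abs(res$interp_frac - (true_frac + pad_extra)), 0.02)
  expect_no_nan(res$x)
})

test_that("canonical responses are removed by regression", {
  fs <- 100
  n <- 60 * fs
  k <- pupil_response_kernel(fs)
  # a trace that is exactly one kernel: residual vanishes
  imp <- numeric(n)
  imp[1000] <- 1
  x <- convolve(imp, rev(k), type = "open")[1:n]
  res <- remove_event_responses(x, fs, blink_times = 999 / fs)
  expect_lt(max(abs(res)), 1e-6 * max(k))

  # no events: unchanged (and reported)
  expect_message(out <- remove_event_responses(x, fs), "no events")
  expect_identical(out, x)

  # 20 events on top of a slow signal: slow signal survives
  set.seed(4)
  slow <- sin(2 * pi * 0.05 * (1:n) / fs)
  ev <- sort(runif(20, 1, 50))
  imp2 <- numeric(n)
  imp2[round(ev * fs) + 1] <- 1
  trace <- slow + 0.8 * convolve(imp2, rev(k), type = "open")[1:n] +
    rnorm(n, sd = 0.01)
  res2 <- remove_event_responses(trace, fs, blink_times = ev)
  expect_gt(cor(res2, slow), 0.99)
})

test_that("band-pass removes DC, attenuates 10 Hz, and derivative works", {
  fs <- 400
  n <- 120 * fs
  # constant input -> zero output
  tr <- bandpass_downsample(rep(7, n), fs)
  expect_lt(max(abs(tr$diameter)), 1e-3 * 7)
  expect_equal(tr$fs, 400)

  # 10 Hz attenuated by >= 20 dB relative to 0.1 Hz
  tt <- (1:n) / fs
  a_slow <- sd(bandpass_downsample(sin(2 * pi * 0.1 * tt), fs)$diameter)
  a_fast <- sd(bandpass_downsample(sin(2 * pi * 10 * tt), fs)$diameter)
  expect_gt(20 * log10(a_slow / a_fast), 20)

  # the derivative is the forward difference scaled by fs: where the
  # filtered trace is locally linear, it equals the local slope
  y <- tr$diameter
  expect_equal(tr$derivative[100], (y[101] - y[100]) * tr$fs,
               tolerance = 1e-12)

  # derivative integrates back to the trace up to a constant
  set.seed(6)
  tr2 <- bandpass_downsample(5 + cumsum(rnorm(n)) / 50, fs)
  m <- length(tr2$diameter)
  recon <- tr2$diameter[1] + cumsum(c(0, tr2$derivative[1:(m - 1)])) / tr2$fs
  err <- max(abs(recon - tr2$diameter)) / sd(tr2$diameter)
  expect_lt(err, 1e-6)
})

test_that("full preprocessing is idempotent up to filter transients", {
  p <- quiet_pupil(duration = 120, seed = 9)
  tr1 <- preprocess_pupil(p)
  tr2 <- bandpass_downsample(tr1$diameter, tr1$fs)
  mid <- seq(round(0.1 * length(tr1$diameter)),
             round(0.9 * length(tr1$diameter)))
  # reapplying the band-pass only re-attenuates band-edge content
  expect_gt(cor(tr1$diameter[mid], tr2$diameter[mid]), 0.995)
})

test_that("pupil spectrum finds the Hippus and is scale invariant", {
  p <- generate_pupil(240, 400, hippus_amp = 1.5, blink_rate_hz = 0,
                      saccade_rate_hz = 0, seed = 11)
  ps <- pupil_spectrum(p$diameter_clean, fs = 400)
  expect_false(is.na(ps$hippus_freq))
  expect_lt(abs(ps$hippus_freq - 0.2), 0.05)

  # doubling the amplitude leaves the standardized spectrum unchanged
  ps2 <- pupil_spectrum(2 * p$diameter_clean, fs = 400)
  expect_equal(ps$psd, ps2$psd, tolerance = 1e-9)

  expect_error(pupil_spectrum(rnorm(100), fs = 400), "10 s")
})

test_that("largest periodic peak sits at the Hippus frequency", {
  # multitaper periodogram oracle on the clean generated trace
  p <- generate_pupil(240, 400, hippus_amp = 1.5, blink_rate_hz = 0,
                      saccade_rate_hz = 0, seed = 13)
  z <- scale(p$diameter_clean)[, 1]
  mt <- pupilflux:::multitaper_psd(z, 400)
  sel <- mt$freq >= 0.1 & mt$freq <= 0.5
  f_peak <- mt$freq[sel][which.max(mt$psd[sel])]
  expect_lt(abs(f_peak - 0.2), 0.05)
})
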