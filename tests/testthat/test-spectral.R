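# Frequency grid, Morlet wavelet envelopes, and segment-wise Welch spectra.

test_that("frequency grid matches its defining relations", {
  g <- freq_grid()
  expect_equal(nrow(g), 25)
  expect_equal(g$center[1], 2)
  expect_equal(g$center[13], 16)             # 2 * 2^(12/4)
  expect_equal(g$center[25], 128)
  expect_equal(g$center, 2 * 2^((0:24) / 4))
  # half-octave band around 8 Hz
  k8 <- which(g$center == 8)
  expect_equal(g$band_lo[k8], 6.727, tolerance = 1e-3)
  expect_equal(g$band_hi[k8], 9.514, tolerance = 1e-3)
  # sigma mapping and 80% overlap
  expect_equal(g$sigma_f, (g$band_hi - g$band_lo) / 2)
  expect_equal(g$sigma_t, 1 / (2 * pi * g$sigma_f))
  expect_equal(g$step_s, 0.2 * 6 * g$sigma_t)
})

test_that("a center-frequency sinusoid has a flat envelope scaling as A^2", {
  fs <- 400
  tt <- (1:(60 * fs)) / fs
  g <- freq_grid()
  k <- which(g$center == 16)
  for (A in c(1, 3)) {
    env <- wavelet_envelopes(A * sin(2 * pi * 16 * tt), fs = fs, grid = g)
    pw <- env$power[[k]][, 1]
    interior <- pw[round(length(pw) * 0.1):round(length(pw) * 0.9)]
    expect_lt(diff(range(interior)) / mean(interior), 0.01)
    if (A == 1) p1 <- mean(interior) else
      expect_equal(mean(interior), A^2 * p1, tolerance = 1e-6)
  }
  # two octaves away: < 1% of the on-band power
  env <- wavelet_envelopes(sin(2 * pi * 16 * tt), fs = fs, grid = g)
  off <- mean(env$power[[which(g$center == 64)]][, 1])
  expect_lt(off / p1, 0.01)
})

test_that("envelope tracks a slow amplitude modulator", {
  fs <- 400
  tt <- (1:(120 * fs)) / fs
  mod <- 1 + 0.5 * sin(2 * pi * 0.2 * tt)
  x <- mod * sin(2 * pi * 16 * tt)
  env <- wavelet_envelopes(x, fs = fs)
  k <- which(env$grid$center == 16)
  mod2 <- (1 + 0.5 * sin(2 * pi * 0.2 * (env$times[[k]] + 1 / fs)))^2
  expect_gt(cor(env$power[[k]][, 1], mod2), 0.95)
})

test_that("wavelet transform is linear at the coefficient level", {
  # parallelogram law |c(x+y)|^2 + |c(x-y)|^2 = 2|c(x)|^2 + 2|c(y)|^2
  # holds iff coefficients are linear in the input
  set.seed(1)
  fs <- 400
  n <- 30 * fs
  x <- rnorm(n)
  y <- rnorm(n)
  g <- freq_grid()[seq(1, 25, by = 6), ]
  class(g) <- c("freq_grid", "data.frame")
  exy <- wavelet_envelopes(cbind(x + y, x - y, x, y), fs = fs, grid = g)
  for (k in seq_len(nrow(g))) {
    p <- exy$power[[k]]
    expect_equal(p[, 1] + p[, 2], 2 * p[, 3] + 2 * p[, 4],
                 tolerance = 1e-8)
  }
})

test_that("window counts and masking behave as specified", {
  fs <- 400
  n <- 40 * fs
  set.seed(2)
  x <- rnorm(n)
  g <- freq_grid()
  env <- wavelet_envelopes(x, fs = fs)
  for (k in c(1, 13, 25)) {
    half <- round(3 * g$sigma_t[k] * fs)
    step <- max(1, round(g$step_s[k] * fs))
    expected <- length(seq(half + 1, n - half, by = step))
    expect_equal(nrow(env$power[[k]]), expected)
    expect_true(all(diff(env$times[[k]]) > 0))
  }
  # windows overlapping masked samples are flagged invalid
  mask <- rep(FALSE, n)
  mask[8000:8400] <- TRUE
  envm <- wavelet_envelopes(x, fs = fs, mask = mask)
  k <- 13
  touching <- env$times[[k]] > 8000 / fs - 3 * g$sigma_t[k] - 0.01 &
    env$times[[k]] < 8400 / fs + 3 * g$sigma_t[k] + 0.01
  expect_true(all(!envm$valid[[k]][touching]))
  expect_true(all(envm$valid[[k]][!touching]))
})

test_that("segment spectra have the stated grid and pairing", {
  p <- quiet_pupil(90, seed = 3)
  tr <- preprocess_pupil(p)
  s <- synth_subject("null", duration_s = 90, n_channels = 1, seed = 3)
  seg <- segment_spectra(s$neural, tr)
  expect_equal(length(seg$freq), 253)              # 2:0.5:128
  expect_equal(seg$freq, seq(2, 128, by = 0.5))
  expect_true(all(seg$psd[[1]] >= 0))

  # shift 0: segment pupil equals the plain per-segment mean
  seg0 <- segment_spectra(s$neural, tr, shift_s = 0)
  i <- 5
  idx <- round(seg0$seg_t[i] * tr$fs) + seq_len(2 * tr$fs)
  expect_equal(seg0$seg_pupil[i], mean(tr$diameter[idx]), tolerance = 1e-12)

  expect_error(segment_spectra(s$neural, tr, seg_len_s = 30), "14 usable")
})

test_that("integrated segment psd satisfies Parseval for a sinusoid", {
  fs <- 400
  tt <- (1:(90 * fs)) / fs
  A <- 2
  x <- A * sin(2 * pi * 10 * tt)
  p <- quiet_pupil(90, seed = 4)
  tr <- preprocess_pupil(p)
  seg <- segment_spectra(matrix(x), tr, fs = fs)
  near <- abs(seg$freq - 10) <= 1.5
  got <- sum(seg$psd[[1]][3, near]) * 0.5          # df = 0.5 Hz
  expect_equal(got, A^2 / 2, tolerance = 0.05 * A^2 / 2)
})
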