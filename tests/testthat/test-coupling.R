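# Gaussian-copula MI, surrogate standardization, lagged cross-correlation,
# spatial binning, and shifted Spearman maps.

test_that("gcmi matches the closed-form Gaussian MI", {
  set.seed(1)
  for (rho in c(0, 0.3, 0.6, 0.9)) {
    truth <- -0.5 * log2(1 - rho^2)
    mis <- replicate(20, {
      x <- rnorm(2e4)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(2e4)
      gcmi(x, y)
    })
    expect_lt(abs(mean(mis) - truth), 0.01)
  }
})

test_that("gcmi is exactly invariant to monotone marginal transforms", {
  set.seed(2)
  x <- rnorm(500)
  y <- 0.5 * x + rnorm(500)
  expect_equal(gcmi(x, y), gcmi(exp(x), -y^3), tolerance = 1e-12)
  expect_error(gcmi(rep(1, 100), rnorm(100)), "constant")
  expect_error(gcmi(x, 2 * x + 3), "degenerate")
  expect_error(gcmi(rnorm(10), rnorm(10)), "50")
})

test_that("surrogate z matches a brute-force surrogate loop exactly", {
  s <- small_linear_subject(duration = 90, seed = 5)
  tr <- preprocess_pupil(s$pupil)
  env <- wavelet_envelopes(s$neural)
  k <- 11                                   # 11.3 Hz
  mi <- mi_with_surrogates(tr, env, n_perm = 25, guard_s = 10, seed = 99)
  # replicate by brute force with the identical RNG draw
  pe <- pupil_at_envelope(tr, NULL, env, k)
  nwin <- length(pe)
  gn <- round(10 / env$step_s[k])
  set.seed(99)
  for (kk in seq_len(nrow(env$grid))) {     # consume draws as the op does
    nw <- length(env$times[[kk]])
    g2 <- round(10 / env$step_s[kk])
    sh <- sample(seq.int(g2, nw - g2), 25, replace = TRUE)
    if (kk == k) shifts <- sh
  }
  obs <- gcmi(env$power[[k]][, 1], pe)
  expect_equal(mi$mi_obs[1, k], obs, tolerance = 1e-10)
  surr <- vapply(shifts, function(sh) {
    pe_s <- c(pe[(sh + 1):nwin], pe[1:sh])  # rotate left by sh
    gcmi(env$power[[k]][, 1], pe_s)
  }, numeric(1))
  z_ref <- (log(obs) - mean(log(surr))) / sd(log(surr))
  expect_equal(mi$mi_z[1, k], z_ref, tolerance = 1e-8)

  # determinism
  mi2 <- mi_with_surrogates(tr, env, n_perm = 25, guard_s = 10, seed = 99)
  expect_identical(mi$mi_z, mi2$mi_z)
})

test_that("a (near-)deterministic monotone envelope gives very large z", {
  # Surrogate log-MI under the null is log-chi-square distributed with an
  # SD near 2.2, so z > 5 demands an observed MI many orders of magnitude
  # above the null: an essentially deterministic monotone envelope. A
  # perfectly deterministic one is a degenerate copula (|rho| = 1, an
  # error by contract), so vanishing noise is added to break rank ties.
  fs <- 400
  p <- generate_pupil(300, fs, blink_rate_hz = 0, saccade_rate_hz = 0,
                      drift_exponent = 0, seed = 6)
  nn <- generate_neural(300, fs, 1, synth_preset("null", seed = 6), p)
  zp <- nn$zpupil
  x <- sin(2 * pi * 16 * (1:length(zp)) / fs)
  env <- wavelet_envelopes(x, fs = fs)
  k <- which(env$grid$center == 16)
  pe <- pupil_at_envelope(zp, fs, env, k)
  set.seed(2)
  env$power[[k]][, 1] <- exp(pe + rnorm(length(pe), sd = 1e-5))
  mi <- mi_with_surrogates(zp, env, n_perm = 100, seed = 1, fs_pupil = fs)
  expect_gt(mi$mi_z[1, k], 5)
  expect_gt(mi$mi_obs[1, k], 10)
})

test_that("cross-correlation satisfies the orientation symmetry", {
  set.seed(7)
  a <- rnorm(400)
  b <- rnorm(400)
  r_ab <- pupilflux:::pearson_xcorr(a, b, 50)
  r_ba <- pupilflux:::pearson_xcorr(b, a, 50)
  expect_equal(r_ab, rev(r_ba), tolerance = 1e-12)
  # spot-check the definition against cor() at a few lags
  for (k in c(-20, 0, 13)) {
    n <- 400
    ref <- if (k >= 0) cor(a[1:(n - k)], b[(1 + k):n])
           else cor(a[(1 - k):n], b[1:(n + k)])
    expect_equal(r_ab[k + 51], ref, tolerance = 1e-12)
  }
})

test_that("white-noise correlograms stay below the analytic null bound", {
  set.seed(8)
  inside <- replicate(20, {
    n <- 2000
    r <- pupilflux:::pearson_xcorr(rnorm(n), rnorm(n), 40)
    max(abs(r)) < 2 / sqrt(n - 40) * sqrt(log(81))  # Bonferroni-ish bound
  })
  expect_gte(mean(inside), 0.9)
})

test_that("an injected envelope lag is recovered at the correct sign", {
  s <- small_linear_subject(duration = 300, seed = 9, gain = 1,
                            lag_s = -0.93)
  tr <- preprocess_pupil(s$pupil)
  env <- wavelet_envelopes(s$neural)
  xc <- xcorr_lagged(tr, env)
  k <- 11
  # generator lag -0.93 (neural leads) -> correlogram extremum at +0.93
  expect_equal(xc$peak_lag[1, k], 0.93, tolerance = 3 * env$step_s[k])
  expect_gt(xc$peak_r[1, k], 0.2)
})

test_that("spatial binning averages and partitions channels correctly", {
  # fabricate an xcorr result whose correlogram is the same linear
  # function of lag at every channel and frequency: band averaging and
  # interpolation must reproduce it exactly at every bin
  g <- freq_grid()
  xc78 <- list(lags = vector("list", 25), r = vector("list", 25),
               peak_lag = matrix(0, 78, 25), peak_r = matrix(0, 78, 25),
               grid = g, step_s = g$step_s)
  class(xc78) <- "xcorr_result"
  f_of_lag <- function(l) 0.3 - 0.02 * l
  for (k in 1:25) {
    L <- floor(5 / g$step_s[k])
    xc78$lags[[k]] <- ((-L):L) * g$step_s[k]
    xc78$r[[k]] <- matrix(rep(f_of_lag(xc78$lags[[k]]), each = 78),
                          nrow = 78)
  }
  bx <- bin_and_average_xcorr(xc78, coords = seq(1, -1, length.out = 78))
  expect_equal(lengths(bx$bin_channels), rep(2L, 39))
  interior <- abs(bx$bands[[2]]$lags) <= 4.5   # clear of edge clamping
  for (b in c(1, 20, 39))
    expect_equal(bx$bands[[2]]$r[b, interior],
                 f_of_lag(bx$bands[[2]]$lags[interior]), tolerance = 1e-12)
  # anterior bins hold the most anterior channels
  expect_equal(sort(bx$bin_channels[[1]]), c(1L, 2L))
  expect_equal(sort(bx$bin_channels[[39]]), c(77L, 78L))
})

test_that("rank correlation maps hit +-1 for monotone envelopes and match
           the lagged Spearman correlation exactly", {
  s <- small_linear_subject(duration = 90, seed = 11)
  tr <- preprocess_pupil(s$pupil)
  env <- wavelet_envelopes(s$neural)
  k <- 11
  pe <- pupil_at_envelope(tr, NULL, env, k)
  kk <- round(0.93 / env$step_s[k])
  # fabricate monotone / anti-monotone envelopes of the shifted pupil
  env2 <- env
  n <- length(pe)
  shifted <- c(pe[(1 + kk):n], rep(0, kk))  # pupil(t + shift)
  env2$power[[k]][, 1] <- exp(shifted)
  rho <- shifted_rho_map(tr, env2, shift_s = 0.93)
  expect_equal(rho$rho[1, k], 1, tolerance = 1e-12)
  env2$power[[k]][, 1] <- -shifted^3
  rho2 <- shifted_rho_map(tr, env2, shift_s = 0.93)
  expect_equal(rho2$rho[1, k], -1, tolerance = 1e-12)

  # pairing contract: map equals Spearman of the explicitly lagged pair
  rho3 <- shifted_rho_map(tr, env, shift_s = 0.93)
  ref <- cor(rank(env$power[[k]][1:(n - kk), 1]),
             rank(pe[(1 + kk):n]))
  expect_equal(rho3$rho[1, k], ref, tolerance = 1e-12)
})
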