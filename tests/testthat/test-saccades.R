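# Microsaccade detection and event-locked spectral / pupil changes.

# gaze with ballistic steps of known onset and velocity
make_gaze <- function(duration = 120, fs = 400, n_events = 40,
                      vel_mult = 5, lambda = 6, noise_sd = 0.02,
                      dur_samples = 8, seed = 1) {
  set.seed(seed)
  n <- duration * fs
  gx <- rnorm(n, sd = noise_sd)
  gy <- rnorm(n, sd = noise_sd)
  onsets <- sort(sample(seq(2 * fs, n - 2 * fs, by = 4), n_events))
  # empirical noise scale of the 5-point velocity estimator
  vv <- (gx[5:n] + gx[4:(n - 1)] - gx[2:(n - 3)] - gx[1:(n - 4)]) * fs / 6
  eta <- sqrt(median(vv^2) - median(vv)^2)
  step_v <- vel_mult * lambda * eta
  amp <- step_v * dur_samples / fs
  for (o in onsets) {
    idx <- o:(o + dur_samples - 1)
    gx[idx] <- gx[idx] + step_v / fs * seq_len(dur_samples)
    gx[(o + dur_samples):n] <- gx[(o + dur_samples):n] + amp
  }
  list(gaze = cbind(gx, gy), onsets = (onsets - 1) / fs, fs = fs)
}

test_that("plain noise and constant gaze yield (almost) no events", {
  ok <- replicate(10, {
    g <- make_gaze(duration = 30, n_events = 0, seed = sample.int(1e6, 1))
    nrow(detect_microsaccades(g$gaze, g$fs)) == 0
  })
  expect_gte(mean(ok), 0.9)
  expect_message(ms <- detect_microsaccades(matrix(1, 1000, 2), 400),
                 "constant")
  expect_equal(nrow(ms), 0)
})

test_that("injected ballistic steps are detected with onset precision", {
  g <- make_gaze(duration = 120, n_events = 40, seed = 2)
  ms <- detect_microsaccades(g$gaze, g$fs)
  # precision and recall with +-12.5 ms matching tolerance
  tol <- 5 / g$fs
  hits <- vapply(g$onsets, function(o) any(abs(ms$onset - o) <= tol),
                 logical(1))
  matched <- vapply(ms$onset, function(o) any(abs(g$onsets - o) <= tol),
                    logical(1))
  expect_gte(mean(hits), 0.9)                        # recall
  expect_gte(mean(matched), 0.9)                     # precision
  expect_true(all(diff(ms$onset) > 0))
  expect_true(all(ms$duration >= 5 / g$fs))
})

test_that("the minimum-duration criterion gates detection", {
  # 20 ms movements smear into suprathreshold velocity runs of ~30 ms:
  # accepted at the 5-sample (12.5 ms) minimum, rejected at 50 ms
  g <- make_gaze(duration = 60, n_events = 25, dur_samples = 8, seed = 3)
  tol <- 5 / g$fs
  recall <- function(ms) mean(vapply(g$onsets, function(o)
    any(abs(ms$onset - o) <= tol), logical(1)))
  expect_gte(recall(detect_microsaccades(g$gaze, g$fs)), 0.9)
  strict <- detect_microsaccades(g$gaze, g$fs, min_dur_samples = 20)
  expect_lte(recall(strict), 0.1)
})

test_that("event-locked percent change is null for stationary signals", {
  set.seed(4)
  fs <- 400
  x <- rnorm(300 * fs)
  events <- sort(runif(100, 5, 295))
  el <- event_locked_power(x, fs, events)
  base_bin <- which.min(abs(el$t_bins + 0.25))
  expect_equal(el$pct_power[base_bin, ], rep(0, ncol(el$pct_power)))
  # no event-locked structure: percent change fluctuates around zero
  # (small positive Jensen bias from the noisy baseline estimate remains)
  m <- rowMeans(el$pct_power[, el$freq >= 8 & el$freq <= 32])
  expect_lt(abs(mean(m)), 5)

  # doubling the amplitude leaves percent change unchanged
  el2 <- event_locked_power(2 * x, fs, events)
  expect_equal(el$pct_power, el2$pct_power, tolerance = 1e-9)

  expect_error(event_locked_power(x, fs, events = c(1, 2)), "10 events")
})

test_that("an injected post-event alpha-beta suppression is recovered", {
  fs <- 400
  n <- 200 * fs
  signs <- replicate(10, {
    seed <- sample.int(1e6, 1)
    set.seed(seed)
    osc <- pupilflux:::narrowband_noise(n, fs, 8, 32)
    osc <- osc / sd(osc)
    events <- sort(runif(40, 5, 195))
    supp <- rep(1, n)
    for (e in events) {
      idx <- round(e * fs):(round(e * fs) + round(0.3 * fs))
      supp[idx] <- 0.4                       # 60% amplitude dip 0-300 ms
    }
    x <- osc * supp + 0.3 * rnorm(n)
    el <- event_locked_power(x, fs, events)
    bins <- el$t_bins > 0 & el$t_bins < 0.3
    mean(el$pct_power[bins, el$freq >= 8 & el$freq <= 32]) < 0
  })
  expect_gte(mean(signs), 0.95)
})

test_that("pupil percent change is computed alongside power", {
  set.seed(5)
  fs <- 400
  x <- rnorm(120 * fs)
  pupil <- 5 + cumsum(rnorm(120 * fs)) / 1e3
  events <- sort(runif(20, 5, 115))
  el <- event_locked_power(x, fs, events, pupil = pupil)
  expect_length(el$pct_pupil, length(el$t_bins))
  base_bin <- which.min(abs(el$t_bins + 0.25))
  expect_equal(el$pct_pupil[base_bin], 0)
})
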