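## Parameter-recovery and calibration studies on synthetic data.
##
## These functions define the package's validation experiments: each one
## generates data with known ground truth, runs the corresponding part of
## the analysis pipeline, and returns the recovery metrics. They are used
## by the test suite and by scripts/acceptance.R.

#' Monte-Carlo error of the Gaussian-copula MI estimator
#'
#' Draws bivariate Gaussian samples at the given correlations and compares
#' the mean estimated MI against the closed form `-0.5 * log2(1 - rho^2)`.
#'
#' @param rhos correlations to test.
#' @param n samples per draw.
#' @param n_seeds Monte-Carlo repetitions per correlation.
#' @param seed RNG seed.
#' @return data frame with `rho`, `truth_bits`, `mean_mi_bits`, `abs_error`.
#' @export
study_gcmi_error <- function(rhos = c(0, 0.3, 0.6, 0.9), n = 5e4,
                             n_seeds = 100, seed = 1L) {
  set.seed(seed)
  out <- lapply(rhos, function(rho) {
    mis <- vapply(seq_len(n_seeds), function(i) {
      x <- stats::rnorm(n)
      y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
      gcmi(x, y)
    }, numeric(1))
    truth <- -0.5 * log2(1 - rho^2)
    data.frame(rho = rho, truth_bits = truth, mean_mi_bits = mean(mis),
               abs_error = abs(mean(mis) - truth))
  })
  do.call(rbind, out)
}

#' Calibration of the time-shift surrogate null
#'
#' Generates zero-coupling subjects, runs the full pupil preprocessing,
#' wavelet envelope and surrogate-MI chain, and summarizes the distribution
#' of standardized MI over all channel x frequency cells. Under a correct
#' null, z is approximately standard normal: the mean should be near 0 and
#' the fraction of |z| > 1.96 near 0.05.
#'
#' @param n_subjects,n_channels,duration_s study geometry.
#' @param n_perm surrogates per cell.
#' @param seed RNG seed.
#' @return list with `z` (all cells), `mean_z`, `fp_rate`, `n_cells`.
#' @export
study_null_calibration <- function(n_subjects = 5, n_channels = 10,
                                   duration_s = 300, n_perm = 200,
                                   seed = 1L) {
  zs <- c()
  for (i in seq_len(n_subjects)) {
    s <- synth_subject("null", duration_s = duration_s, fs_hz = 400,
                       n_channels = n_channels,
                       seed = subject_seed(seed, i))
    tr <- preprocess_pupil(s$pupil)
    env <- wavelet_envelopes(s$neural)
    mi <- mi_with_surrogates(tr, env, n_perm = n_perm,
                             seed = subject_seed(seed, i) + 1L)
    zs <- c(zs, as.vector(mi$mi_z))
  }
  list(z = zs, mean_z = mean(zs), fp_rate = mean(abs(zs) > 1.96),
       n_cells = length(zs))
}

#' Recovery of injected envelope-pupil lags
#'
#' Injects band-limited oscillations coupled to the pupil at known lags
#' (one lag per frequency band, rotated across seeds so every lag x band
#' combination occurs), recovers each band's extremum lag from the channel-
#' and band-averaged cross-correlogram via [binned_peak_lag()], and scores
#' a recovery as successful when the error is at most one envelope sample
#' of the band's highest center frequency. The pupil is artifact-free here:
#' this study validates the lag estimator, not the artifact handling.
#'
#' @param n_seeds number of simulated recordings.
#' @param lags injected lags in seconds (generator convention: negative =
#'   neural leads; the recovered correlogram extremum sits at `-lag`).
#' @param bands list of frequency bands (Hz).
#' @param n_channels channels per recording (averaged before peak-picking).
#' @param duration_s recording length (s).
#' @param gain injected linear coupling gain.
#' @param seed RNG seed.
#' @return list with `errors_s`, `errors_samples`, `success_rate`, `table`
#'   (per seed x band: injected lag, recovered lag, tolerance).
#' @export
study_lag_recovery <- function(n_seeds = 50, lags = c(-0.93, -0.5, 0.2),
                               bands = list(c(2, 4), c(8, 16), c(64, 128)),
                               n_channels = 8, duration_s = 300, gain = 1,
                               seed = 1L) {
  g_full <- freq_grid()
  ks <- sort(unique(unlist(lapply(bands, grid_band_idx, grid = g_full))))
  g <- g_full[ks, ]
  class(g) <- c("freq_grid", "data.frame")
  rows <- NULL
  for (i in seq_len(n_seeds)) {
    rot <- i %% length(lags)
    lag_for_band <- lags[((seq_along(bands) - 1 + rot) %% length(lags)) + 1]
    cp <- do.call(rbind, lapply(seq_along(bands), function(j)
      data.frame(group = "all",
                 center_hz = g_full$center[grid_band_idx(g_full, bands[[j]])],
                 gain = gain, quad = 0, lag_s = lag_for_band[j])))
    gt <- ground_truth(cp, blink_rate_hz = 0, saccade_rate_hz = 0,
                       seed = subject_seed(seed, i))
    s <- synth_subject(gt, duration_s = duration_s, fs_hz = 400,
                       n_channels = n_channels,
                       seed = subject_seed(seed, i))
    tr <- preprocess_pupil(s$pupil)
    env <- wavelet_envelopes(s$neural, grid = g)
    xc <- xcorr_lagged(tr, env)
    bx <- bin_and_average_xcorr(xc, s$neural$coords, bands = bands,
                                n_bins = 1)
    pk <- binned_peak_lag(bx)
    for (j in seq_along(bands)) {
      kref <- which.max(g$center * (g$center >= bands[[j]][1] &
                                      g$center <= bands[[j]][2]))
      tol <- env$step_s[kref]
      rows <- rbind(rows, data.frame(
        seed_i = i, band_lo = bands[[j]][1], band_hi = bands[[j]][2],
        lag_injected = lag_for_band[j], lag_true = -lag_for_band[j],
        lag_recovered = pk$peak_lag[j], tol_s = tol))
    }
  }
  err <- rows$lag_recovered - rows$lag_true
  list(errors_s = err, errors_samples = err / rows$tol_s,
       success_rate = mean(abs(err) <= rows$tol_s + 1e-9), table = rows)
}

#' Group-level recovery of an injected inverted-U coupling
#'
#' Simulates subjects with a negative quadratic envelope coupling at
#' 11.3 Hz (the 8-16 Hz band), runs segment spectra, band power, pupil
#' binning and the quadratic model, and performs the group test with FDR
#' control over all frequency cells.
#'
#' @param n_subjects simulated subjects.
#' @param duration_s recording length (s).
#' @param quad injected quadratic coefficient (negative = inverted-U).
#' @param q FDR level.
#' @param seed RNG seed.
#' @return list with `test` (`group_test`), `centers`, `injected_idx`
#'   (centers whose half-octave band overlaps the injected oscillation),
#'   `control_idx` (centers in the 2-4 and 64-128 Hz bands),
#'   `fp_fraction` (FDR rejections among control centers), `mean_beta2`.
#' @export
study_quadratic_recovery <- function(n_subjects = 20, duration_s = 300,
                                     quad = -0.5, q = 0.1, seed = 1L) {
  grid <- freq_grid()
  subs <- lapply(seq_len(n_subjects), function(i) {
    gt <- ground_truth(data.frame(group = "all", center_hz = 11.3137,
                                  gain = 0, quad = quad, lag_s = -0.93),
                       seed = subject_seed(seed, i))
    s <- synth_subject(gt, duration_s = duration_s, fs_hz = 400,
                       n_channels = 1, seed = subject_seed(seed, i))
    tr <- preprocess_pupil(s$pupil)
    seg <- segment_spectra(s$neural, tr)
    bp <- segment_band_power(seg, grid = grid)
    list(values = bp$power, pupil = seg$seg_pupil, centers = bp$centers)
  })
  qm <- quad_map(lapply(subs, function(s) s[c("values", "pupil")]), q = q)
  centers <- subs[[1]]$centers
  inj_lo <- 11.3137 * 2^(-1 / 4)
  inj_hi <- 11.3137 * 2^(1 / 4)
  injected <- which(grid$band_hi >= inj_lo & grid$band_lo <= inj_hi)
  control <- which((centers >= 2 & centers <= 4) |
                     (centers >= 64 & centers <= 128))
  list(test = qm$test, centers = centers, injected_idx = injected,
       control_idx = control,
       fp_fraction = mean(qm$test$reject[control]),
       mean_beta2 = qm$test$mean)
}

#' Recovery of the aperiodic exponent from synthetic spectra
#'
#' Noiseless power-law spectra across a grid of exponents, the same with a
#' compliant Gaussian peak added, and noisy 2 s Welch segments of true
#' 1/f^chi noise.
#'
#' @param chis exponents for the noiseless scan.
#' @param chi_noisy exponent for the segment-noise study.
#' @param n_segments number of noisy 2 s segments.
#' @param seed RNG seed.
#' @return list with `noiseless_max_err`, `peak_perturbation`,
#'   `noisy_bias`, `noisy_mean`.
#' @export
study_exponent_recovery <- function(chis = c(0.5, 1, 1.5, 2, 2.5, 3),
                                    chi_noisy = 1.5, n_segments = 500,
                                    seed = 1L) {
  f <- seq(3, 40, by = 0.5)
  errs <- vapply(chis, function(chi)
    abs(fit_spectrum(10^(1 - chi * log10(f)), f)$exponent - chi),
    numeric(1))
  ## compliant Gaussian peak: 10 Hz, height 0.3, width 4 Hz (= 2 sigma)
  pert <- vapply(chis, function(chi) {
    y <- 1 - chi * log10(f) + 0.3 * exp(-(f - 10)^2 / (2 * 2^2))
    abs(fit_spectrum(10^y, f)$exponent - chi)
  }, numeric(1))
  set.seed(seed)
  fs <- 400
  x <- powerlaw_noise(n_segments * 2 * fs, fs, chi_noisy)
  starts <- seq(1, length(x) - 2 * fs + 1, by = 2 * fs)
  ex <- vapply(starts, function(s) {
    p <- welch_segment_psd(x[s:(s + 2 * fs - 1)], fs)
    fit_spectrum(p$psd, p$freq)$exponent
  }, numeric(1))
  list(noiseless_max_err = max(errs), peak_perturbation = max(pert),
       noisy_bias = abs(mean(ex) - chi_noisy), noisy_mean = mean(ex))
}

#' Recovery of aperiodic-exponent coupling and its separation from
#' oscillatory coupling
#'
#' Two experiments. Slope-only: subjects with a negative exponent-pupil
#' slope and no oscillations; per-subject Pearson correlation between the
#' per-segment fitted exponent and pupil should be negative, while
#' residualized (aperiodic-subtracted) band power should not couple to
#' pupil. Peak-only: subjects with a linear envelope coupling at 11.3 Hz
#' and fixed exponent; residualized band power should couple positively at
#' 11.3 Hz and not at 4 Hz.
#'
#' @param n_subjects subjects for the slope-only experiment.
#' @param n_peak_subjects subjects for the peak-only experiment.
#' @param duration_s recording length (s).
#' @param seed RNG seed.
#' @return list with `slope_r` (per subject), `frac_negative`,
#'   `slope_residual_mean_r` (per center, group mean), `peak_r_11`,
#'   `peak_r_4` (group means), `centers`.
#' @export
study_exponent_coupling <- function(n_subjects = 20, n_peak_subjects = 5,
                                    duration_s = 300, seed = 1L) {
  grid <- freq_grid()
  slope_r <- numeric(n_subjects)
  resid_r <- NULL
  for (i in seq_len(n_subjects)) {
    s <- synth_subject("slope", duration_s = duration_s, fs_hz = 400,
                       n_channels = 1, seed = subject_seed(seed, i))
    tr <- preprocess_pupil(s$pupil)
    seg <- segment_spectra(s$neural, tr)
    es <- exponent_series(seg)
    slope_r[i] <- es$r_pupil
    rb <- residual_band_power(seg, es$fits, grid = grid)
    resid_r <- rbind(resid_r, rb$r_pupil)
    centers <- rb$centers
  }
  peak_r <- NULL
  for (i in seq_len(n_peak_subjects)) {
    s <- synth_subject("linear", duration_s = duration_s, fs_hz = 400,
                       n_channels = 1, seed = subject_seed(seed + 101L, i))
    tr <- preprocess_pupil(s$pupil)
    seg <- segment_spectra(s$neural, tr)
    es <- exponent_series(seg)
    rb <- residual_band_power(seg, es$fits, grid = grid)
    peak_r <- rbind(peak_r, rb$r_pupil)
  }
  k11 <- which.min(abs(centers - 11.3137))
  k4 <- which.min(abs(centers - 4))
  list(slope_r = slope_r, frac_negative = mean(slope_r < 0),
       slope_residual_mean_r = colMeans(resid_r),
       peak_r_11 = mean(peak_r[, k11]), peak_r_4 = mean(peak_r[, k4]),
       centers = centers)
}

#' Microsaccade detection accuracy on synthetic gaze
#'
#' Gaze noise with ballistic steps whose peak velocity is a fixed multiple
#' of the detection threshold; precision and recall are scored with a
#' +/- 12.5 ms onset tolerance.
#'
#' @param duration_s gaze duration (s).
#' @param n_events injected events.
#' @param vel_mult peak velocity as a multiple of the `lambda * eta`
#'   threshold.
#' @param fs sampling rate.
#' @param seed RNG seed.
#' @return list with `precision`, `recall`, `n_detected`, `n_true`.
#' @export
study_saccade_detection <- function(duration_s = 120, n_events = 40,
                                    vel_mult = 5, fs = 400, seed = 1L) {
  set.seed(seed)
  n <- duration_s * fs
  gx <- stats::rnorm(n, sd = 0.02)
  gy <- stats::rnorm(n, sd = 0.02)
  onsets <- sort(sample(seq(2L * fs, n - 2L * fs, by = 4L), n_events))
  vv <- (gx[5:n] + gx[4:(n - 1)] - gx[2:(n - 3)] - gx[1:(n - 4)]) * fs / 6
  eta <- sqrt(stats::median(vv^2) - stats::median(vv)^2)
  step_v <- vel_mult * 6 * eta
  dur_n <- 8L                                  # 20 ms at 400 Hz
  for (o in onsets) {
    idx <- o:(o + dur_n - 1L)
    gx[idx] <- gx[idx] + step_v / fs * seq_len(dur_n)
    gx[(o + dur_n):n] <- gx[(o + dur_n):n] + step_v * dur_n / fs
  }
  ms <- detect_microsaccades(cbind(gx, gy), fs)
  onsets_s <- (onsets - 1) / fs
  tol <- 5 / fs
  recall <- mean(vapply(onsets_s, function(o)
    any(abs(ms$onset - o) <= tol), logical(1)))
  precision <- if (nrow(ms)) mean(vapply(ms$onset, function(o)
    any(abs(onsets_s - o) <= tol), logical(1))) else 0
  list(precision = precision, recall = recall, n_detected = nrow(ms),
       n_true = n_events)
}

#' Sign recovery of microsaccade-locked oscillatory suppression
#'
#' Injects a transient 8-32 Hz amplitude suppression 0-300 ms after each
#' event and checks that the event-locked percent change in that band and
#' window is negative.
#'
#' @param n_runs independent simulations.
#' @param duration_s recording length per run (s).
#' @param seed RNG seed.
#' @return list with `sign_rate` (fraction of runs recovering the negative
#'   sign) and `mean_pct` (mean suppression, percent).
#' @export
study_saccade_suppression <- function(n_runs = 20, duration_s = 200,
                                      seed = 1L) {
  fs <- 400
  n <- duration_s * fs
  res <- vapply(seq_len(n_runs), function(i) {
    set.seed(subject_seed(seed, i))
    osc <- narrowband_noise(n, fs, 8, 32)
    osc <- osc / stats::sd(osc)
    events <- sort(stats::runif(40, 5, duration_s - 5))
    supp <- rep(1, n)
    for (e in events) {
      idx <- round(e * fs):(round(e * fs) + round(0.3 * fs))
      supp[idx] <- 0.4
    }
    x <- osc * supp + 0.3 * stats::rnorm(n)
    el <- event_locked_power(x, fs, events)
    bins <- el$t_bins > 0 & el$t_bins < 0.3
    mean(el$pct_power[bins, el$freq >= 8 & el$freq <= 32])
  }, numeric(1))
  list(sign_rate = mean(res < 0), mean_pct = mean(res))
}
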