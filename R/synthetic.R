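## Synthetic pupil + multichannel neural recordings with known ground truth.
##
## The generator emulates the statistical structure the analysis pipeline is
## designed to detect: a slow arousal process read out by pupil diameter
## (band-limited 0.005-2 Hz, with a narrowband Hippus component near 0.2 Hz,
## blink gaps and saccade-locked transients), and neural channels whose
## 1/f^chi aperiodic background and band-limited oscillation envelopes couple
## to the lagged, z-scored pupil trace linearly and/or quadratically.

#' Ground-truth parameters for a synthetic recording
#'
#' Defines the coupling structure injected into synthetic neural channels.
#' Linear gain, quadratic coefficient and lag are settable independently per
#' channel group and frequency band via the `couplings` table.
#'
#' @param couplings data frame with columns `group` (`"all"`, `"anterior"` or
#'   `"posterior"`), `center_hz` (oscillation band center; half-octave band),
#'   `gain` (linear envelope-pupil gain per unit z-pupil), `quad` (quadratic
#'   coefficient; negative = inverted-U), `lag_s` (seconds; the oscillation
#'   amplitude at time t follows z-pupil at `t - lag_s`, so negative lags mean
#'   the neural signal leads the pupil).
#' @param exponent_base baseline aperiodic exponent chi0 (power ~ 1/f^chi).
#' @param exponent_slope change in chi per unit z-pupil (at the same lag
#'   convention), 0 for no aperiodic coupling.
#' @param exponent_lag_s lag for the aperiodic coupling, seconds.
#' @param hippus_freq_hz Hippus center frequency (Hz).
#' @param hippus_amp Hippus amplitude (SD units relative to the slow drift).
#' @param blink_rate_hz blink events per second.
#' @param saccade_rate_hz gaze saccade events per second.
#' @param osc_amp oscillation baseline amplitude (SD units).
#' @param seed RNG seed stored with the dataset.
#' @return object of class `ground_truth`.
#' @seealso [synth_preset()], [generate_neural()], [write_manifest()]
#' @export
ground_truth <- function(couplings = NULL,
                         exponent_base = 1.5, exponent_slope = 0,
                         exponent_lag_s = -0.93,
                         hippus_freq_hz = 0.2, hippus_amp = 0.3,
                         blink_rate_hz = 0.25, saccade_rate_hz = 1,
                         osc_amp = 1, seed = 1L) {
  if (is.null(couplings)) {
    couplings <- data.frame(group = character(), center_hz = numeric(),
                            gain = numeric(), quad = numeric(),
                            lag_s = numeric())
  }
  stopifnot(all(c("group", "center_hz", "gain", "quad", "lag_s") %in%
                  names(couplings)))
  stopifnot(all(couplings$center_hz >= 2 & couplings$center_hz <= 128))
  gt <- list(couplings = couplings,
             exponent_base = exponent_base,
             exponent_slope = exponent_slope,
             exponent_lag_s = exponent_lag_s,
             hippus_freq_hz = hippus_freq_hz, hippus_amp = hippus_amp,
             blink_rate_hz = blink_rate_hz,
             saccade_rate_hz = saccade_rate_hz,
             osc_amp = osc_amp, seed = as.integer(seed))
  class(gt) <- "ground_truth"
  gt
}

#' Write / read a ground-truth manifest (JSON)
#'
#' The manifest is written beside every synthetic dataset and is the only
#' source of expected values for downstream recovery tests; serialization
#' round-trips losslessly.
#'
#' @param gt a [ground_truth()] object.
#' @param path file path for the JSON manifest.
#' @export
write_manifest <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cp <- as.data.frame(raw$couplings, stringsAsFactors = FALSE)
  if (nrow(cp) == 0)
    cp <- data.frame(group = character(), center_hz = numeric(),
                     gain = numeric(), quad = numeric(), lag_s = numeric())
  ground_truth(couplings = cp,
               exponent_base = raw$exponent_base,
               exponent_slope = raw$exponent_slope,
               exponent_lag_s = raw$exponent_lag_s,
               hippus_freq_hz = raw$hippus_freq_hz,
               hippus_amp = raw$hippus_amp,
               blink_rate_hz = raw$blink_rate_hz,
               saccade_rate_hz = raw$saccade_rate_hz,
               osc_amp = raw$osc_amp, seed = raw$seed)
}

#' Preset ground-truth configurations
#'
#' Named coupling scenarios used throughout validation:
#' \describe{
#'   \item{null}{no coupling of any kind (calibration of surrogate nulls).}
#'   \item{linear}{linear envelope coupling, gain +0.5 at 11.3 Hz,
#'     lag -0.93 s (neural leads pupil).}
#'   \item{quadratic}{inverted-U coupling, quadratic coefficient -0.5 at
#'     11.3 Hz, no linear term.}
#'   \item{slope}{aperiodic-exponent coupling only, -0.2 chi per z-pupil.}
#'   \item{full}{low-frequency negative and high-frequency positive linear
#'     coupling, inverted-U at 11.3 Hz, negative exponent slope; the 11.3 Hz
#'     linear coupling has opposite sign in anterior vs posterior channels.}
#' }
#' @param name one of `"null"`, `"linear"`, `"quadratic"`, `"slope"`, `"full"`.
#' @param seed RNG seed stored in the returned object.
#' @return a [ground_truth()].
#' @export
synth_preset <- function(name = c("null", "linear", "quadratic", "slope",
                                  "full"), seed = 1L) {
  name <- match.arg(name)
  cp <- function(...) data.frame(..., stringsAsFactors = FALSE)
  gt <- switch(name,
    null = ground_truth(seed = seed),
    linear = ground_truth(
      cp(group = "all", center_hz = 11.3137, gain = 0.5, quad = 0,
         lag_s = -0.93), seed = seed),
    quadratic = ground_truth(
      cp(group = "all", center_hz = 11.3137, gain = 0, quad = -0.5,
         lag_s = -0.93), seed = seed),
    slope = ground_truth(exponent_slope = -0.2, seed = seed),
    full = ground_truth(
      cp(group = c("all", "anterior", "posterior", "all"),
         center_hz = c(2.8284, 11.3137, 11.3137, 90.5097),
         gain = c(-0.5, -0.5, 0.5, 0.5),
         quad = c(0, -0.5, -0.5, 0),
         lag_s = c(-0.93, -0.93, -0.93, -0.93)),
      exponent_slope = -0.2, seed = seed)
  )
  attr(gt, "preset") <- name
  gt
}

#' Generate a synthetic pupil / gaze recording
#'
#' Pupil diameter is the sum of a band-limited (0.005-2 Hz) slow drift, a
#' narrowband Hippus oscillation, canonical dilation responses locked to
#' gaze saccades, and blink artifacts (NaN gaps of 100-400 ms with a biphasic
#' recovery deflection). Gaze traces contain fixation noise plus ballistic
#' saccade steps at Poisson times.
#'
#' @param duration_s recording length in seconds (>= 60).
#' @param fs_hz sampling rate (>= 100).
#' @param hippus_freq_hz Hippus center frequency (Hz).
#' @param hippus_bw_hz Hippus bandwidth (Hz).
#' @param hippus_amp Hippus SD relative to the unit-SD slow drift; 0 disables.
#' @param blink_rate_hz blink events per second; 0 disables blinks.
#' @param saccade_rate_hz saccade events per second; 0 disables saccades.
#' @param drift_exponent spectral exponent of the slow drift inside the
#'   0.005-2 Hz band (default 2, matching the steep spectra of spontaneous
#'   pupil recordings).
#' @param seed optional RNG seed.
#' @return list of class `pupil_raw` with elements `t`, `diameter` (NaN in
#'   blink gaps), `diameter_clean` (artifact-free), `gaze_x`, `gaze_y`, `fs`,
#'   `blink_onsets`, `blink_durations`, `saccade_onsets` (seconds).
#' @export
generate_pupil <- function(duration_s, fs_hz = 400, hippus_freq_hz = 0.2,
                           hippus_bw_hz = 0.05, hippus_amp = 0.3,
                           blink_rate_hz = 0.25, saccade_rate_hz = 1,
                           drift_exponent = 2, seed = NULL) {
  if (!is.numeric(duration_s) || duration_s < 60)
    stop("duration_s must be >= 60 s")
  if (!is.numeric(fs_hz) || fs_hz < 100)
    stop("fs_hz must be >= 100 Hz")
  if (!is.null(seed)) set.seed(seed)
  fs <- fs_hz
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  ## slow arousal drift: steep (1/f^2) in-band spectrum, as in real pupil
  ## recordings, so most variance sits below ~0.1 Hz
  slow <- zerophase_butter(powerlaw_noise(n, fs, drift_exponent), fs,
                           lo = 0.005, hi = 2)
  slow <- slow / stats::sd(slow)
  hip <- 0
  if (hippus_amp > 0) {
    hip <- narrowband_noise(n, fs, hippus_freq_hz - hippus_bw_hz / 2,
                            hippus_freq_hz + hippus_bw_hz / 2)
    hip <- hippus_amp * hip / stats::sd(hip)
  }
  diameter_clean <- 5 + slow + hip

  ## gaze: fixation noise + slow drift + ballistic saccade steps (20 ms)
  gx <- 0.02 * stats::rnorm(n) + 0.1 * {
    d <- zerophase_butter(stats::rnorm(n), fs, lo = NULL, hi = 0.5); d / stats::sd(d)
  }
  gy <- 0.02 * stats::rnorm(n) + 0.1 * {
    d <- zerophase_butter(stats::rnorm(n), fs, lo = NULL, hi = 0.5); d / stats::sd(d)
  }
  saccade_onsets <- numeric(0)
  if (saccade_rate_hz > 0) {
    n_sac <- stats::rpois(1, saccade_rate_hz * duration_s)
    saccade_onsets <- sort(stats::runif(n_sac, 2, duration_s - 3))
    ramp_n <- max(2L, round(0.02 * fs))          # 20 ms ballistic ramp
    ramp <- (1 - cos(pi * seq_len(ramp_n) / ramp_n)) / 2
    for (on in saccade_onsets) {
      amp <- stats::runif(1, 0.2, 1)
      th <- stats::runif(1, 0, 2 * pi)
      i0 <- round(on * fs) + 1L
      idx <- i0:(i0 + ramp_n - 1L)
      gx[idx] <- gx[idx] + amp * cos(th) * ramp
      gx[(idx[ramp_n] + 1L):n] <- gx[(idx[ramp_n] + 1L):n] + amp * cos(th)
      gy[idx] <- gy[idx] + amp * sin(th) * ramp
      gy[(idx[ramp_n] + 1L):n] <- gy[(idx[ramp_n] + 1L):n] + amp * sin(th)
    }
  }

  ## saccade-locked pupil dilation via the canonical kernel
  if (length(saccade_onsets)) {
    k <- pupil_response_kernel(fs)
    imp <- numeric(n)
    imp[pmin(n, round(saccade_onsets * fs) + 1L)] <- 1
    resp <- stats::convolve(imp, rev(k), type = "open")[seq_len(n)]
    diameter_clean <- diameter_clean + 0.1 * resp
  }

  diameter <- diameter_clean
  blink_onsets <- numeric(0)
  blink_durations <- numeric(0)
  if (blink_rate_hz > 0) {
    n_bl <- stats::rpois(1, blink_rate_hz * duration_s)
    blink_onsets <- sort(stats::runif(n_bl, 2, duration_s - 3))
    blink_durations <- stats::runif(n_bl, 0.1, 0.4)
    rec_n <- round(0.6 * fs)
    tt <- seq_len(rec_n) / fs
    recovery <- -(exp(-tt / 0.08) - 1.6 * exp(-tt / 0.25))  # biphasic
    for (j in seq_along(blink_onsets)) {
      i0 <- round(blink_onsets[j] * fs) + 1L
      i1 <- min(n, i0 + round(blink_durations[j] * fs))
      diameter[i0:i1] <- NaN
      idx <- (i1 + 1L):min(n, i1 + rec_n)
      diameter[idx] <- diameter[idx] + 0.4 * recovery[seq_along(idx)]
    }
  }

  out <- list(t = t, diameter = diameter, diameter_clean = diameter_clean,
              gaze_x = gx, gaze_y = gy, fs = fs,
              blink_onsets = blink_onsets, blink_durations = blink_durations,
              saccade_onsets = saccade_onsets)
  class(out) <- "pupil_raw"
  out
}

## circularly shift a vector so element i of the result is x[i - k] (k in
## samples; k < 0 advances the series)
shift_circular <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1L):n], x[seq_len(n - k)])
}

#' Generate synthetic multichannel neural time series
#'
#' Each channel is the sum of an aperiodic 1/f^chi(t) background, whose
#' exponent varies slowly with the lagged z-scored pupil
#' (`chi(t) = chi0 + exponent_slope * zpupil(t - lag)`), and band-limited
#' oscillations (narrowband-filtered noise on the half-octave band around
#' each coupling's center) whose instantaneous amplitude follows
#' `baseline * max(0, 1 + gain * zp(t - lag) + quad * zp(t - lag)^2)`.
#' Channel coordinates span an anterior (+1) to posterior (-1) axis;
#' couplings with `group = "anterior"`/`"posterior"` apply to the
#' corresponding half of the channels.
#'
#' The background is synthesized by filtering white noise with an FFT-domain
#' `f^(-chi/2)` amplitude mask in overlapping Hann-weighted windows so the
#' exponent can track the pupil; each window's mask is normalized to unit
#' RMS gain over 3-40 Hz so exponent changes tilt rather than rescale the
#' spectrum.
#'
#' @param duration_s recording length (s); must match `pupil`.
#' @param fs_hz sampling rate (Hz).
#' @param n_channels number of channels.
#' @param ground_truth a [ground_truth()] object.
#' @param pupil a `pupil_raw` object from [generate_pupil()] at `fs_hz`, or a
#'   numeric vector already on the neural time grid.
#' @param chi_window_s window length for the time-varying-exponent synthesis.
#' @param seed optional RNG seed (defaults to `ground_truth$seed`).
#' @return list of class `neural_ts` with `x` (time x channels matrix), `fs`,
#'   `t`, `coords` (anterior-posterior coordinate per channel), `zpupil`
#'   (the z-scored 0.005-2 Hz pupil trace used in the coupling equations).
#' @export
generate_neural <- function(duration_s, fs_hz, n_channels, ground_truth,
                            pupil, chi_window_s = 4, seed = NULL) {
  gt <- ground_truth
  stopifnot(inherits(gt, "ground_truth"))
  fs <- fs_hz
  n <- round(duration_s * fs)
  lags <- c(gt$couplings$lag_s, gt$exponent_lag_s)
  if (length(lags) && max(abs(lags)) >= duration_s)
    stop("coupling lag must be smaller than the recording duration")
  if (!is.null(seed)) set.seed(seed) else set.seed(gt$seed)

  pd <- if (inherits(pupil, "pupil_raw")) pupil$diameter_clean else pupil
  if (length(pd) != n)
    stop("pupil must be sampled on the neural time grid")
  zp <- zerophase_butter(pd, fs, lo = 0.005, hi = 2)
  zp <- (zp - mean(zp)) / stats::sd(zp)

  coords <- if (n_channels == 1) 0 else seq(1, -1, length.out = n_channels)
  in_group <- function(group) {
    switch(group,
           all = rep(TRUE, n_channels),
           anterior = coords > 0,
           posterior = coords <= 0,
           stop("unknown channel group: ", group))
  }

  ## time-varying aperiodic background, overlap-add of masked white noise
  wlen <- 2L * (round(chi_window_s * fs) %/% 2L)
  hop <- wlen %/% 2L
  win <- hann_window(wlen)
  fgrid <- fs * (0:(wlen - 1)) / wlen
  fgrid <- pmin(fgrid, fs - fgrid)
  band_idx <- which(fgrid >= 3 & fgrid <= 40)
  starts <- seq(1L, n - wlen + 1L, by = hop)
  chi_lag_n <- round(gt$exponent_lag_s * fs)
  zp_chi <- shift_circular(zp, chi_lag_n)

  x <- matrix(0, n, n_channels)
  wsum <- numeric(n)
  white <- matrix(stats::rnorm(n * n_channels), n, n_channels)
  for (s in starts) {
    idx <- s:(s + wlen - 1L)
    chi_w <- gt$exponent_base +
      gt$exponent_slope * zp_chi[s + hop]      # window-center pupil state
    mask <- ifelse(fgrid > 0, fgrid^(-chi_w / 2), 0)
    mask <- mask / sqrt(mean(mask[band_idx]^2))
    for (ch in seq_len(n_channels)) {
      seg <- Re(stats::fft(stats::fft(white[idx, ch]) * mask,
                           inverse = TRUE)) / wlen
      x[idx, ch] <- x[idx, ch] + seg * win
    }
    wsum[idx] <- wsum[idx] + win
  }
  ok <- wsum > 1e-3
  x[ok, ] <- x[ok, ] / wsum[ok]
  x[!ok, ] <- 0

  ## band-limited oscillations with pupil-coupled envelopes
  if (nrow(gt$couplings)) {
    for (r in seq_len(nrow(gt$couplings))) {
      cpl <- gt$couplings[r, ]
      chans <- which(in_group(cpl$group))
      if (!length(chans)) next
      zp_l <- shift_circular(zp, round(cpl$lag_s * fs))
      am <- pmax(0, 1 + cpl$gain * zp_l + cpl$quad * zp_l^2)
      lo <- cpl$center_hz * 2^(-1 / 4)
      hi <- cpl$center_hz * 2^(1 / 4)
      for (ch in chans) {
        carrier <- narrowband_noise(n, fs, lo, hi)
        carrier <- carrier / stats::sd(carrier)
        x[, ch] <- x[, ch] + gt$osc_amp * carrier * am
      }
    }
  }

  out <- list(x = x, fs = fs, t = (seq_len(n) - 1) / fs, coords = coords,
              zpupil = zp, ground_truth = gt)
  class(out) <- "neural_ts"
  out
}

#' Generate a complete synthetic subject
#'
#' Convenience wrapper producing a pupil recording and coupled neural
#' channels from a preset or explicit ground truth, with a deterministic
#' seed. Optionally writes the ground-truth manifest.
#'
#' @param gt a [ground_truth()] or preset name accepted by [synth_preset()].
#' @param duration_s,fs_hz,n_channels recording geometry.
#' @param seed RNG seed for this subject.
#' @param manifest_path optional path; if given, the manifest is written.
#' @return list of class `synth_subject` with `pupil`, `neural`,
#'   `ground_truth`.
#' @export
synth_subject <- function(gt = "full", duration_s = 300, fs_hz = 400,
                          n_channels = 4, seed = 1L, manifest_path = NULL) {
  if (is.character(gt)) gt <- synth_preset(gt, seed = seed)
  gt$seed <- as.integer(seed)
  pupil <- generate_pupil(duration_s, fs_hz,
                          hippus_freq_hz = gt$hippus_freq_hz,
                          hippus_amp = gt$hippus_amp,
                          blink_rate_hz = gt$blink_rate_hz,
                          saccade_rate_hz = gt$saccade_rate_hz,
                          seed = seed)
  neural <- generate_neural(duration_s, fs_hz, n_channels, gt, pupil,
                            seed = seed + 1L)
  if (!is.null(manifest_path)) write_manifest(gt, manifest_path)
  out <- list(pupil = pupil, neural = neural, ground_truth = gt)
  class(out) <- "synth_subject"
  out
}
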