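## Pupil preprocessing: blink interpolation, canonical event-response
## removal, zero-phase 0.005-2 Hz band-pass, resampling to the analysis
## rate, and first temporal derivative.

#' Convert pupil area to diameter
#'
#' Linearizes a pupil-area readout to diameter, `d = 2 * sqrt(area / pi)`.
#' Non-finite samples (blink gaps) are preserved.
#'
#' @param area numeric vector of pupil areas (>= 0 where finite).
#' @return diameter vector, same length.
#' @examples
#' area_to_diameter(pi)  # 2
#' @export
area_to_diameter <- function(area) {
  if (any(area < 0, na.rm = TRUE))
    stop("negative pupil area encountered")
  2 * sqrt(area / pi)
}

#' Canonical pupil impulse-response kernel
#'
#' Gamma-family kernel `h(t) = t^w * exp(-t / tau)`, normalized to unit
#' peak; with the defaults the peak dilation occurs at `w * tau = 0.93` s,
#' the canonical latency of the pupil response to arousing events.
#'
#' @param fs sampling rate (Hz).
#' @param w shape parameter (default 10.1).
#' @param tau scale (s); default `0.93 / w` so that the peak sits at 0.93 s.
#' @param t_max kernel support in seconds (default 4).
#' @return numeric kernel sampled at `fs`.
#' @export
pupil_response_kernel <- function(fs, w = 10.1, tau = 0.93 / 10.1,
                                  t_max = 4) {
  tt <- seq(0, t_max, by = 1 / fs)
  h <- tt^w * exp(-tt / tau)
  h / max(h)
}

## dilate a logical mask by m samples on each side
dilate_mask <- function(mask, m) {
  if (m <= 0 || !any(mask)) return(mask)
  n <- length(mask)
  idx <- which(mask)
  out <- logical(n)
  for (i in idx) out[max(1, i - m):min(n, i + m)] <- TRUE
  out
}

## linearly interpolate masked samples (edges held at nearest valid value)
interp_masked <- function(x, mask) {
  if (!any(mask)) return(x)
  good <- which(!mask)
  if (!length(good)) stop("trace entirely artifactual")
  x[mask] <- stats::approx(good, x[good], xout = which(mask), rule = 2)$y
  x
}

#' Detect and interpolate blinks and eye-tracker artifacts
#'
#' First pass: runs of non-finite (or sentinel-valued) samples are treated as
#' blink gaps, padded by a margin on each side, and linearly interpolated.
#' Second pass: residual spikes/jumps are found by velocity thresholding
#' (`|dx/dt| > k * MAD`), padded by a shorter margin, and interpolated.
#' Every replaced sample is marked in the interpolation mask.
#'
#' @param x raw pupil series (diameter or area) with NaN/sentinel gaps.
#' @param fs sampling rate (Hz).
#' @param pad_s padding margin around detected gaps (s, default 0.15).
#' @param spike_k velocity-outlier threshold in MAD units (default 16).
#' @param spike_pad_s padding around velocity outliers (s, default 0.05).
#' @param sentinel optional sentinel value also treated as missing.
#' @param max_interp_frac ceiling on the interpolated fraction (default 0.5);
#'   exceeding it is an error.
#' @return list with `x` (gap-free trace), `interp_mask` (logical),
#'   `interp_frac`.
#' @export
detect_and_interpolate_blinks <- function(x, fs, pad_s = 0.15, spike_k = 16,
                                          spike_pad_s = 0.05,
                                          sentinel = NULL,
                                          max_interp_frac = 0.5) {
  n <- length(x)
  bad <- !is.finite(x)
  if (!is.null(sentinel)) bad <- bad | (x == sentinel & is.finite(x))
  if (all(bad)) stop("trace entirely artifactual")
  mask <- dilate_mask(bad, round(pad_s * fs))
  x1 <- interp_masked(x, mask)

  ## second pass: velocity outliers on the interpolated trace; both
  ## endpoints of an outlying sample-to-sample jump are marked
  v <- diff(x1) * fs
  sc <- stats::mad(v)
  if (sc > max(1e-9 * stats::sd(v), 0)) {
    out_v <- abs(v - stats::median(v)) > spike_k * sc
    spikes <- c(out_v, FALSE) | c(FALSE, out_v)
    spikes <- dilate_mask(spikes, round(spike_pad_s * fs))
    spikes <- spikes & !mask
    if (any(spikes)) {
      x1 <- interp_masked(x1, spikes | mask)
      mask <- mask | spikes
    }
  }
  frac <- mean(mask)
  if (frac > max_interp_frac)
    stop(sprintf("interpolated fraction %.2f exceeds ceiling %.2f",
                 frac, max_interp_frac))
  list(x = x1, interp_mask = mask, interp_frac = frac)
}

#' Remove canonical event responses from a pupil trace
#'
#' Builds event regressors by convolving blink / saccade impulse trains with
#' the canonical pupil impulse-response kernel, fits their amplitudes jointly
#' by least squares (one amplitude per event type, plus an intercept), and
#' subtracts the fitted responses.
#'
#' @param x gap-free pupil series.
#' @param fs sampling rate (Hz).
#' @param blink_times,saccade_times event onset times in seconds (within the
#'   trace span); either may be empty.
#' @param kernel canonical kernel (default [pupil_response_kernel()] at `fs`).
#' @return residual trace, same length as `x`.
#' @export
remove_event_responses <- function(x, fs, blink_times = numeric(0),
                                   saccade_times = numeric(0),
                                   kernel = pupil_response_kernel(fs)) {
  n <- length(x)
  all_t <- c(blink_times, saccade_times)
  if (!length(all_t)) {
    message("no events supplied; trace returned unchanged")
    return(x)
  }
  if (any(all_t < 0 | all_t > n / fs))
    stop("event times outside the trace span")
  regressor <- function(times) {
    imp <- numeric(n)
    imp[pmin(n, round(times * fs) + 1L)] <- 1
    stats::convolve(imp, rev(kernel), type = "open")[seq_len(n)]
  }
  X <- matrix(1, n, 1)
  if (length(blink_times)) X <- cbind(X, blink = regressor(blink_times))
  if (length(saccade_times)) X <- cbind(X, sacc = regressor(saccade_times))
  beta <- stats::lm.fit(X, x)$coefficients
  beta[!is.finite(beta)] <- 0
  fitted_events <- X[, -1, drop = FALSE] %*% beta[-1]
  x - as.numeric(fitted_events)
}

#' Band-pass, resample and differentiate a pupil trace
#'
#' Zero-phase 0.005-2 Hz band-pass (second-order Butterworth magnitude,
#' forward-reverse two-pass equivalent), resampling to the analysis rate
#' (default 400 Hz; the 2 Hz low-pass already prevents aliasing), and the
#' first-order forward-difference derivative (last sample repeated).
#'
#' @param x gap-free pupil series.
#' @param fs input sampling rate (Hz).
#' @param band pass band in Hz (default `c(0.005, 2)`).
#' @param fs_out output analysis rate (default 400 Hz).
#' @param interp_mask optional logical mask of interpolated input samples,
#'   carried through resampling.
#' @param allow_upsample if the input rate is below `fs_out`, upsample only
#'   when `TRUE` (default), otherwise keep the input rate with a warning.
#' @return object of class `pupil_trace`: list with `t`, `diameter`
#'   (band-passed), `derivative` (a.u./s), `fs`, `interp_mask`, `provenance`.
#' @export
bandpass_downsample <- function(x, fs, band = c(0.005, 2), fs_out = 400,
                                interp_mask = NULL, allow_upsample = TRUE) {
  stopifnot(all(is.finite(x)))
  if (fs < fs_out && !allow_upsample) {
    warning("input rate below the analysis rate; keeping input rate")
    fs_out <- fs
  } else if (fs < fs_out) {
    warning("input rate below the analysis rate; upsampling")
  }
  y <- zerophase_butter(x, fs, lo = band[1], hi = band[2], order = 2)
  n <- length(y)
  if (fs_out != fs) {
    t_in <- (seq_len(n) - 1) / fs
    n_out <- floor((n - 1) / fs * fs_out) + 1L
    t_out <- (seq_len(n_out) - 1) / fs_out
    y <- stats::approx(t_in, y, xout = t_out)$y
    if (!is.null(interp_mask))
      interp_mask <- stats::approx(t_in, as.numeric(interp_mask),
                                   xout = t_out)$y > 0
  }
  if (is.null(interp_mask)) interp_mask <- rep(FALSE, length(y))
  deriv <- c(diff(y), 0) * fs_out
  deriv[length(deriv)] <- deriv[length(deriv) - 1]
  out <- list(t = (seq_along(y) - 1) / fs_out, diameter = y,
              derivative = deriv, fs = fs_out, interp_mask = interp_mask,
              provenance = c(sprintf("bandpass %.3f-%.1f Hz two-pass",
                                     band[1], band[2]),
                             sprintf("resample %.0f Hz", fs_out),
                             "forward-difference derivative"))
  class(out) <- "pupil_trace"
  out
}

#' Full pupil preprocessing chain
#'
#' Blink/spike interpolation, canonical blink- and saccade-response removal,
#' zero-phase band-pass and resampling, derivative. The standard entry point
#' from a raw recording to an analysis-ready [bandpass_downsample()] trace.
#'
#' @param raw a `pupil_raw` object ([generate_pupil()]) or a numeric vector.
#' @param fs sampling rate when `raw` is a plain vector.
#' @param fs_out analysis rate (default 400).
#' @param remove_responses subtract canonical blink/saccade responses
#'   (default `TRUE`; requires event times, available on `pupil_raw` input).
#' @param ... passed to [detect_and_interpolate_blinks()].
#' @return a `pupil_trace`.
#' @export
preprocess_pupil <- function(raw, fs = NULL, fs_out = 400,
                             remove_responses = TRUE, ...) {
  if (inherits(raw, "pupil_raw")) {
    x <- raw$diameter
    fs <- raw$fs
    blink_t <- raw$blink_onsets
    sacc_t <- raw$saccade_onsets
  } else {
    stopifnot(!is.null(fs))
    x <- raw
    blink_t <- sacc_t <- numeric(0)
  }
  cl <- detect_and_interpolate_blinks(x, fs, ...)
  y <- cl$x
  if (remove_responses && (length(blink_t) || length(sacc_t)))
    y <- remove_event_responses(y, fs, blink_t, sacc_t)
  tr <- bandpass_downsample(y, fs, fs_out = fs_out,
                            interp_mask = cl$interp_mask)
  tr$provenance <- c("blink interpolation",
                     if (remove_responses) "event-response removal",
                     tr$provenance)
  tr
}

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf("<pupil_trace> %.1f s at %g Hz, %.1f%% interpolated\n",
              length(x$diameter) / x$fs, x$fs, 100 * mean(x$interp_mask)))
  cat("steps:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Multitaper pupil spectrum and Hippus parameterization
#'
#' Multitaper power spectrum of the standardized (z-scored) pupil trace with
#' +/- 0.035 Hz spectral smoothing on a zero-padded grid of at least 2^19
#' samples, evaluated at log-spaced frequencies in 0.005-2 Hz, followed by
#' an aperiodic + peaks parameterization (at most 3 peaks, detection
#' threshold 0.5 SD, peak widths 0.1-0.5 Hz). Returns the Hippus peak
#' frequency (largest detected peak) and the pupil spectral exponent.
#'
#' @param x pupil series (a `pupil_trace` or numeric vector).
#' @param fs sampling rate when `x` is a vector.
#' @param half_bw_hz multitaper smoothing half-bandwidth (Hz).
#' @param n_eval number of log-spaced evaluation frequencies.
#' @return list with `freq`, `psd`, `fit` (an `aperiodic_fit`),
#'   `hippus_freq` (Hz or `NA` if no peak), `exponent`.
#' @export
pupil_spectrum <- function(x, fs = NULL, half_bw_hz = 0.035, n_eval = 120) {
  if (inherits(x, "pupil_trace")) {
    fs <- x$fs
    x <- x$diameter
  }
  stopifnot(!is.null(fs))
  dur <- length(x) / fs
  if (dur < 10) stop("trace shorter than 10 s")
  if (dur < 60) warning("trace shorter than 60 s; spectrum unreliable")
  z <- (x - mean(x)) / stats::sd(x)
  mt <- multitaper_psd(z, fs, half_bw_hz = half_bw_hz)
  f_eval <- exp(seq(log(0.005), log(2), length.out = n_eval))
  psd <- stats::approx(mt$freq, mt$psd, xout = f_eval)$y
  fit <- fit_spectrum(psd, f_eval, fit_range = c(0.005, 2), max_peaks = 3,
                      min_height = 0.05, peak_threshold = 0.5,
                      width_bounds = c(0.1, 0.5))
  hip <- if (nrow(fit$peaks)) fit$peaks$center[which.max(fit$peaks$height)]
         else NA_real_
  list(freq = f_eval, psd = psd, fit = fit, hippus_freq = hip,
       exponent = fit$exponent)
}
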