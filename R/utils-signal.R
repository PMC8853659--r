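## Shared signal-processing primitives used across modules.

#' Zero-phase Butterworth filter via its two-pass magnitude response
#'
#' Applies the squared magnitude response of an analog Butterworth filter
#' (the response a forward-reverse two-pass digital filter realizes) in the
#' frequency domain, after even-reflection padding to suppress edge
#' discontinuities. This keeps the filter numerically exact for pass bands
#' reaching down to millihertz cutoffs, where pole locations of a recursive
#' realization become degenerate at typical sampling rates.
#'
#' @param x numeric vector, finite.
#' @param fs sampling rate in Hz.
#' @param lo lower cutoff in Hz (`NULL` for a pure low-pass).
#' @param hi upper cutoff in Hz (`NULL` for a pure high-pass).
#' @param order Butterworth order of each one-pass prototype (default 2).
#' @return filtered vector, same length as `x`.
#' @keywords internal
zerophase_butter <- function(x, fs, lo = NULL, hi = NULL, order = 2) {
  stopifnot(is.numeric(x), all(is.finite(x)), fs > 0)
  if (is.null(lo) && is.null(hi)) return(x)
  n <- length(x)
  xp <- c(x, rev(x))                       # even extension, circularly smooth
  m <- 2L * n
  f <- fs * (0:(m - 1)) / m
  f <- pmin(f, fs - f)                     # fold to [0, fs/2]
  h2 <- if (!is.null(lo) && !is.null(hi)) {
    u <- (f^2 - lo * hi) / (f * (hi - lo))
    u[f == 0] <- Inf
    1 / (1 + u^(2 * order))
  } else if (is.null(lo)) {
    1 / (1 + (f / hi)^(2 * order))
  } else {
    v <- ifelse(f == 0, Inf, lo / f)
    1 / (1 + v^(2 * order))
  }
  ## two passes -> squared magnitude
  y <- Re(stats::fft(stats::fft(xp) * h2, inverse = TRUE)) / m
  y[seq_len(n)]
}

#' @keywords internal
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' One-sided Welch periodogram from a single tapered window
#'
#' Power spectral density of one segment using a periodic Hann taper,
#' normalized so that the integral of the PSD over frequency recovers the
#' signal variance (one-sided convention).
#'
#' @param x numeric segment.
#' @param fs sampling rate (Hz).
#' @param nfft FFT length (default `length(x)`).
#' @return list with `freq` (Hz) and `psd` (power/Hz).
#' @keywords internal
welch_segment_psd <- function(x, fs, nfft = length(x)) {
  n <- length(x)
  w <- hann_window(n)
  xw <- (x - mean(x)) * w
  X <- stats::fft(c(xw, rep(0, nfft - n)))
  nf <- nfft %/% 2 + 1
  p <- (Mod(X[seq_len(nf)])^2) / (fs * sum(w^2))
  p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
  list(freq = fs * (0:(nf - 1)) / nfft, psd = p)
}

#' Averaged Welch PSD over successive segments
#' @keywords internal
welch_psd <- function(x, fs, seg_len, overlap = 0.5) {
  n <- length(x)
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  acc <- NULL
  for (s in starts) {
    p <- welch_segment_psd(x[s:(s + seg_len - 1L)], fs)
    acc <- if (is.null(acc)) p$psd else acc + p$psd
  }
  list(freq = fs * (0:(seg_len %/% 2)) / seg_len, psd = acc / length(starts))
}

#' Band-limited Gaussian noise via spectral masking
#' @keywords internal
narrowband_noise <- function(n, fs, lo, hi, order = 4) {
  zerophase_butter(stats::rnorm(n), fs, lo = lo, hi = hi, order = order)
}

#' Gaussian noise with a 1/f^chi power spectrum
#' @keywords internal
powerlaw_noise <- function(n, fs, chi) {
  x <- stats::rnorm(n)
  f <- fs * (0:(n - 1)) / n
  f <- pmin(f, fs - f)
  mask <- ifelse(f > 0, f^(-chi / 2), 0)
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

#' Multitaper PSD with sine tapers
#'
#' Sine-taper multitaper estimate with a chosen half-bandwidth of spectral
#' smoothing, zero-padded to `nfft` for a common frequency grid across
#' recordings of different lengths.
#'
#' @param x numeric vector (will be demeaned).
#' @param fs sampling rate (Hz).
#' @param half_bw_hz half-bandwidth of the spectral smoothing (Hz).
#' @param nfft FFT length (zero-padding), default next power of two `>= 2^19`.
#' @return list with `freq`, `psd`, `n_tapers`.
#' @keywords internal
multitaper_psd <- function(x, fs, half_bw_hz = 0.035, nfft = NULL) {
  n <- length(x)
  if (is.null(nfft)) nfft <- max(2^19, 2^ceiling(log2(n)))
  k_max <- max(1L, round(2 * half_bw_hz * (n + 1) / fs - 1))
  x <- x - mean(x)
  idx <- seq_len(n)
  nf <- nfft %/% 2 + 1
  acc <- numeric(nf)
  for (k in seq_len(k_max)) {
    taper <- sqrt(2 / (n + 1)) * sin(pi * k * idx / (n + 1))
    X <- stats::fft(c(x * taper, rep(0, nfft - n)))
    acc <- acc + Mod(X[seq_len(nf)])^2
  }
  psd <- acc / (k_max * fs)
  psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  list(freq = fs * (0:(nf - 1)) / nfft, psd = psd, n_tapers = k_max)
}

#' Circular cross-products of two equal-length vectors at every shift
#'
#' Returns `s[k+1] = sum_i x[i] * y[shift(i, k)]` for k = 0..n-1, where
#' `shift(i, k)` indexes y rotated left by k samples. Computed by FFT.
#' @keywords internal
circular_crossprod <- function(x, y) {
  n <- length(x)
  Re(stats::fft(Conj(stats::fft(x)) * stats::fft(y), inverse = TRUE)) / n
}

#' Linear cross-products sum_i x[i] y[i+k] for k = -max_lag..max_lag
#' @keywords internal
linear_crossprod <- function(x, y, max_lag) {
  n <- length(x)
  m <- stats::nextn(2L * n, 2)
  cc <- Re(stats::fft(Conj(stats::fft(c(x, rep(0, m - n)))) *
                        stats::fft(c(y, rep(0, m - n))), inverse = TRUE)) / m
  ks <- (-max_lag):max_lag
  cc[ifelse(ks >= 0, ks + 1L, m + ks + 1L)]
}
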