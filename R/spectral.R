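## Frequency-resolved power envelopes via Morlet wavelets and segment-wise
## Welch spectra for spectral parameterization.

#' Morlet wavelet power envelopes
#'
#' Complex Morlet coefficients
#' `w(t, f) = (sigma_t * sqrt(pi))^(-1/2) * exp(-t^2 / (2 sigma_t^2)) * exp(-i 2 pi f t)`
#' are computed at successive window centers for every grid frequency
#' (wavelet truncated at `+/- 3 sigma_t`, unit-energy normalized); the power
#' envelope is the squared magnitude. Windows are spaced by 20% of the
#' wavelet support (80% overlap); windows requiring samples beyond the
#' recording are dropped, and windows overlapping masked samples are flagged
#' invalid.
#'
#' @param x numeric vector or time x channels matrix, or a `neural_ts`.
#' @param fs sampling rate (Hz); taken from `x` when it is a `neural_ts`.
#' @param grid a [freq_grid()] (default `freq_grid()`).
#' @param mask optional logical vector of artifactual samples.
#' @return object of class `envelope_stack`: list with per-frequency
#'   elements `power` (list of windows x channels matrices), `times` (list of
#'   window-center seconds), `valid` (list of logical vectors), `step_s`
#'   (realized per-frequency envelope step, s), `grid`, `fs`, `n_channels`.
#' @export
wavelet_envelopes <- function(x, fs = NULL, grid = freq_grid(),
                              mask = NULL) {
  if (inherits(x, "neural_ts")) {
    fs <- x$fs
    x <- x$x
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  stopifnot(!is.null(fs))
  n <- nrow(x)
  nch <- ncol(x)
  if (n / fs < 10 * max(grid$sigma_t))
    stop("recording too short for the lowest grid frequency")
  if (is.null(mask)) mask <- rep(FALSE, n)
  cmask <- cumsum(mask)

  nfft <- stats::nextn(n + 2L * max(round(3 * grid$sigma_t * fs)) + 1L, 2)
  X <- matrix(0 + 0i, nfft, nch)
  for (ch in seq_len(nch)) X[, ch] <- stats::fft(c(x[, ch], rep(0, nfft - n)))

  power <- times <- valid <- vector("list", nrow(grid))
  step_real <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    st <- grid$sigma_t[k]
    f0 <- grid$center[k]
    half <- round(3 * st * fs)
    tt <- (-half:half) / fs
    w <- exp(-tt^2 / (2 * st^2)) * exp(-1i * 2 * pi * f0 * tt)
    w <- w / sqrt(sum(Mod(w)^2))                     # unit energy
    ## full convolution with conj(reversed wavelet) = correlation with w
    W <- stats::fft(c(Conj(rev(w)), rep(0 + 0i, nfft - length(w))))
    step_n <- max(1L, round(grid$step_s[k] * fs))
    step_real[k] <- step_n / fs
    centers <- seq(half + 1L, n - half, by = step_n)
    if (!length(centers))
      stop("no valid windows at ", signif(f0, 4), " Hz")
    conv_idx <- centers + half                       # center-aligned output
    coef <- matrix(0 + 0i, length(centers), nch)
    for (ch in seq_len(nch)) {
      full <- stats::fft(X[, ch] * W, inverse = TRUE) / nfft
      coef[, ch] <- full[conv_idx]
    }
    power[[k]] <- Mod(coef)^2
    times[[k]] <- (centers - 1) / fs
    nbad <- cmask[pmin(n, centers + half)] -
      c(0, cmask)[pmax(1L, centers - half)]
    valid[[k]] <- nbad == 0
  }
  out <- list(power = power, times = times, valid = valid,
              step_s = step_real, grid = grid, fs = fs, n_channels = nch)
  class(out) <- "envelope_stack"
  out
}

#' @export
print.envelope_stack <- function(x, ...) {
  cat(sprintf(
    "<envelope_stack> %d channels x %d frequencies (%.3g-%.4g Hz)\n",
    x$n_channels, nrow(x$grid), min(x$grid$center), max(x$grid$center)))
  cat(sprintf("  windows per frequency: %d (lowest) ... %d (highest)\n",
              nrow(x$power[[1]]), nrow(x$power[[length(x$power)]])))
  invisible(x)
}

#' Resample a pupil trace to an envelope's per-frequency time base
#'
#' Averages the pupil signal over each wavelet window support, matching the
#' temporal smoothing of the corresponding envelope samples.
#'
#' @param pupil numeric pupil series (or a `pupil_trace`; use `field` to pick
#'   diameter or derivative).
#' @param fs_pupil sampling rate of `pupil` when it is a vector.
#' @param env an `envelope_stack`.
#' @param k frequency index into the stack.
#' @param field `"diameter"` or `"derivative"` for `pupil_trace` input.
#' @return numeric vector aligned with `env$times[[k]]`.
#' @export
pupil_at_envelope <- function(pupil, fs_pupil = NULL, env, k,
                              field = "diameter") {
  if (inherits(pupil, "pupil_trace")) {
    fs_pupil <- pupil$fs
    pupil <- pupil[[field]]
  }
  stopifnot(!is.null(fs_pupil))
  half_s <- 3 * env$grid$sigma_t[k]
  cs <- c(0, cumsum(pupil))
  n <- length(pupil)
  i0 <- pmax(1L, round(env$times[[k]] * fs_pupil) + 1L -
               round(half_s * fs_pupil))
  i1 <- pmin(n, round(env$times[[k]] * fs_pupil) + 1L +
               round(half_s * fs_pupil))
  (cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1L)
}

#' Segment-wise Welch spectra paired with segment-mean pupil values
#'
#' Splits the neural recording into non-overlapping segments (default 2 s),
#' computes a single Hann-tapered Welch spectrum per segment on a 0.5 Hz
#' grid from 2 to 128 Hz, and pairs each segment with the mean pupil
#' diameter over the segment window shifted forward by `shift_s` (default
#' 0.93 s, the canonical neuro-pupil lag) and the mean pupil derivative over
#' the unshifted window. Segments extending past either recording are
#' dropped.
#'
#' @param neural a `neural_ts`, or time x channels matrix.
#' @param pupil a `pupil_trace` (or numeric vector at `fs_pupil`).
#' @param fs,fs_pupil sampling rates for matrix/vector input.
#' @param seg_len_s segment length (s, default 2).
#' @param shift_s forward shift applied to the pupil diameter (s).
#' @param overlap fractional segment overlap (default 0, non-overlapping).
#' @param f_range spectral range (Hz, default `c(2, 128)`).
#' @return object of class `segmented_spectra`: `psd` (list per channel of
#'   segments x frequency matrices), `freq`, `seg_t` (segment starts, s),
#'   `seg_pupil`, `seg_pupil_deriv`, `fs`, `n_channels`, `shift_s`.
#' @export
segment_spectra <- function(neural, pupil, fs = NULL, fs_pupil = NULL,
                            seg_len_s = 2, shift_s = 0.93, overlap = 0,
                            f_range = c(2, 128)) {
  if (inherits(neural, "neural_ts")) {
    fs <- neural$fs
    neural <- neural$x
  }
  if (is.null(dim(neural))) neural <- matrix(neural, ncol = 1)
  stopifnot(!is.null(fs))
  if (inherits(pupil, "pupil_trace")) {
    fs_pupil <- pupil$fs
    pderiv <- pupil$derivative
    pupil <- pupil$diameter
  } else {
    stopifnot(!is.null(fs_pupil))
    pderiv <- c(diff(pupil), 0) * fs_pupil
    pderiv[length(pderiv)] <- pderiv[length(pderiv) - 1]
  }
  n <- nrow(neural)
  nch <- ncol(neural)
  seg_n <- round(seg_len_s * fs)
  step_n <- max(1L, round(seg_n * (1 - overlap)))
  starts <- seq(1L, n - seg_n + 1L, by = step_n)
  np <- length(pupil)

  ## drop segments whose (shifted) pupil window leaves the pupil recording
  keep <- vapply(starts, function(s) {
    t0 <- (s - 1) / fs
    p0 <- round((t0 + shift_s) * fs_pupil) + 1L
    p1 <- p0 + round(seg_len_s * fs_pupil) - 1L
    q0 <- round(t0 * fs_pupil) + 1L
    q1 <- q0 + round(seg_len_s * fs_pupil) - 1L
    p0 >= 1 && p1 <= np && q0 >= 1 && q1 <= np
  }, logical(1))
  starts <- starts[keep]
  if (length(starts) < 14)
    stop("fewer than 14 usable segments; pupil-binned analyses impossible")

  fr <- welch_segment_psd(neural[starts[1]:(starts[1] + seg_n - 1L), 1], fs)
  fsel <- which(fr$freq >= f_range[1] - 1e-9 & fr$freq <= f_range[2] + 1e-9)
  freq <- fr$freq[fsel]

  psd <- lapply(seq_len(nch), function(ch)
    matrix(0, length(starts), length(fsel)))
  seg_pupil <- seg_deriv <- numeric(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    for (ch in seq_len(nch)) {
      p <- welch_segment_psd(neural[s:(s + seg_n - 1L), ch], fs)
      psd[[ch]][i, ] <- p$psd[fsel]
    }
    t0 <- (s - 1) / fs
    p0 <- round((t0 + shift_s) * fs_pupil) + 1L
    q0 <- round(t0 * fs_pupil) + 1L
    m <- round(seg_len_s * fs_pupil)
    seg_pupil[i] <- mean(pupil[p0:(p0 + m - 1L)])
    seg_deriv[i] <- mean(pderiv[q0:(q0 + m - 1L)])
  }
  out <- list(psd = psd, freq = freq, seg_t = (starts - 1) / fs,
              seg_pupil = seg_pupil, seg_pupil_deriv = seg_deriv,
              fs = fs, n_channels = nch, seg_len_s = seg_len_s,
              shift_s = shift_s)
  class(out) <- "segmented_spectra"
  out
}

#' @export
print.segmented_spectra <- function(x, ...) {
  cat(sprintf(
    "<segmented_spectra> %d segments x %d freqs (%g-%g Hz), %d channel(s)\n",
    length(x$seg_t), length(x$freq), min(x$freq), max(x$freq),
    x$n_channels))
  cat(sprintf("  segment %g s, pupil shift %g s\n", x$seg_len_s, x$shift_s))
  invisible(x)
}

#' Per-segment band power on the wavelet grid
#'
#' Mean Welch power of each segment over each half-octave band of the grid
#' whose center lies within `range_hz`. Used by the quadratic pupil-power
#' model and the residualized coupling analysis.
#'
#' @param seg a `segmented_spectra`.
#' @param grid a [freq_grid()].
#' @param channel channel index.
#' @param range_hz restrict to centers within this range.
#' @return list with `power` (segments x centers), `centers`.
#' @export
segment_band_power <- function(seg, grid = freq_grid(), channel = 1,
                               range_hz = c(2, 128)) {
  ks <- which(grid$center >= range_hz[1] - 1e-9 &
                grid$center <= range_hz[2] + 1e-9)
  pw <- sapply(ks, function(k) {
    sel <- seg$freq >= grid$band_lo[k] & seg$freq <= grid$band_hi[k]
    rowMeans(seg$psd[[channel]][, sel, drop = FALSE])
  })
  list(power = pw, centers = grid$center[ks])
}
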