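## Pupil-power coupling: Gaussian-copula mutual information standardized
## against time-shift surrogates, lagged cross-correlation of amplitude
## envelopes, and forward-shifted Spearman correlation maps.

## rank-to-Gaussian copula transform
copula_transform <- function(v) {
  stats::qnorm(rank(v, ties.method = "average") / (length(v) + 1))
}

#' Gaussian-copula mutual information
#'
#' Rank-transforms each variable to uniform margins, maps them through the
#' inverse standard-normal CDF, and returns the Gaussian mutual information
#' `-0.5 * log2(1 - rho^2)` of the transformed pair, where `rho` is their
#' empirical correlation. Invariant to monotone transforms of either margin;
#' sensitive to monotonic and non-monotonic dependence alike when used on
#' envelope data via surrogate standardization.
#'
#' @param x,y paired numeric vectors (finite, non-constant, n >= 50).
#' @return mutual information in bits.
#' @examples
#' set.seed(1)
#' x <- rnorm(5000); y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(5000)
#' gcmi(x, y)  # close to -0.5 * log2(1 - 0.36) = 0.322 bits
#' @export
gcmi <- function(x, y) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (length(x) < 50) stop("need at least 50 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input has undefined copula")
  r <- stats::cor(copula_transform(x), copula_transform(y))
  if (abs(r) >= 1 - 1e-12) stop("degenerate copula (|rho| = 1)")
  -0.5 * log2(1 - r^2)
}

#' Standardized MI between pupil and power envelopes via time-shift surrogates
#'
#' For every channel and grid frequency, the pupil trace is averaged onto
#' the envelope's per-frequency time base, both series are copula-
#' transformed, and the observed Gaussian-copula MI is standardized against
#' `n_perm` surrogate MIs obtained by circularly time-shifting the pupil
#' series by random offsets drawn uniformly outside a guard window of
#' `guard_s` seconds around zero shift:
#' `z = (log MI_obs - mean(log MI_surr)) / sd(log MI_surr)`.
#'
#' Because the copula scores of a circularly shifted series are the shifted
#' copula scores, all surrogate correlations are obtained exactly from one
#' FFT-based circular cross-correlation per channel and frequency.
#'
#' @param pupil a `pupil_trace` (or numeric vector with `fs_pupil`).
#' @param env an `envelope_stack`.
#' @param n_perm number of surrogates (default 200).
#' @param guard_s guard window around zero shift (s, default 10).
#' @param seed RNG seed for the surrogate shifts.
#' @param fs_pupil sampling rate when `pupil` is a vector.
#' @param field pupil field to use (`"diameter"` or `"derivative"`).
#' @return object of class `mi_result`: `mi_z` and `mi_obs`
#'   (channels x frequencies), `n_perm`, `guard_s`, `grid`.
#' @export
mi_with_surrogates <- function(pupil, env, n_perm = 200, guard_s = 10,
                               seed = 1L, fs_pupil = NULL,
                               field = "diameter") {
  stopifnot(inherits(env, "envelope_stack"))
  set.seed(seed)
  nf <- nrow(env$grid)
  nch <- env$n_channels
  mi_z <- mi_obs <- matrix(NaN, nch, nf)
  for (k in seq_len(nf)) {
    pe <- pupil_at_envelope(pupil, fs_pupil, env, k, field = field)
    nwin <- length(pe)
    gn <- round(guard_s / env$step_s[k])
    if (nwin - gn <= gn) stop("recording shorter than twice the guard window")
    shifts <- sample(seq.int(gn, nwin - gn), n_perm, replace = TRUE)
    yg <- copula_transform(pe)
    my <- mean(yg); sy <- stats::sd(yg) * sqrt((nwin - 1) / nwin)
    for (ch in seq_len(nch)) {
      xg <- copula_transform(env$power[[k]][, ch])
      mx <- mean(xg); sx <- stats::sd(xg) * sqrt((nwin - 1) / nwin)
      ## circular correlation at every shift in one FFT
      cc <- circular_crossprod(xg, yg) / nwin
      r_all <- (cc - mx * my) / (sx * sy)
      r_all <- pmin(pmax(r_all, -1 + 1e-12), 1 - 1e-12)
      mi_all <- -0.5 * log2(1 - r_all^2)
      mi_obs[ch, k] <- mi_all[1]
      ls <- log(mi_all[shifts + 1L])
      sdl <- stats::sd(ls)
      mi_z[ch, k] <- if (sdl == 0) NaN else (log(mi_all[1]) - mean(ls)) / sdl
    }
  }
  out <- list(mi_z = mi_z, mi_obs = mi_obs, n_perm = n_perm,
              guard_s = guard_s, grid = env$grid)
  class(out) <- "mi_result"
  out
}

## exact per-lag Pearson correlation r(k) = cor(a[t], b[t + k]),
## k = -max_lag..max_lag samples, via cumulative sums + FFT cross-products
pearson_xcorr <- function(a, b, max_lag, min_n = 2L) {
  n <- length(a)
  stopifnot(length(b) == n, max_lag < n)
  cp <- linear_crossprod(a, b, max_lag)        # sum a[i] b[i+k]
  csa <- cumsum(a); csa2 <- cumsum(a^2)
  csb <- cumsum(b); csb2 <- cumsum(b^2)
  ks <- (-max_lag):max_lag
  r <- numeric(length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    m <- n - abs(k)
    if (m < min_n) { r[j] <- NaN; next }
    if (k >= 0) {            # a[1:(n-k)] vs b[(1+k):n]
      sa <- csa[m]; sa2 <- csa2[m]
      sb <- csb[n] - if (k > 0) csb[k] else 0
      sb2 <- csb2[n] - if (k > 0) csb2[k] else 0
    } else {                 # a[(1-k+1)...]: a[(|k|+1):n] vs b[1:m]
      sa <- csa[n] - csa[-k]; sa2 <- csa2[n] - csa2[-k]
      sb <- csb[m]; sb2 <- csb2[m]
    }
    num <- cp[j] - sa * sb / m
    den <- sqrt(max(sa2 - sa^2 / m, 0) * max(sb2 - sb^2 / m, 0))
    r[j] <- if (den <= 0) NaN else num / den
  }
  r
}

#' Lagged cross-correlation between pupil and power envelopes
#'
#' Computes the Pearson correlation `r(tau) = cor(power(t), pupil(t + tau))`
#' for lags up to `max_lag_s`, per channel and frequency, after averaging
#' the pupil onto each envelope's per-frequency time base. Positive lags
#' indicate the neural signal preceding the pupil, negative lags the pupil
#' preceding the neural signal. The signed extremum of `r` within
#' `peak_range_s` gives the per-cell peak lag.
#'
#' @param pupil a `pupil_trace` or numeric vector (`fs_pupil` required).
#' @param env an `envelope_stack`.
#' @param max_lag_s maximum lag (s, default 10).
#' @param peak_range_s lag range searched for the extremum (s, default 5).
#' @param min_overlap_s minimum overlap after lagging (s, default 30); lags
#'   with less overlap get `NaN`.
#' @param fs_pupil sampling rate when `pupil` is a vector.
#' @param field pupil field (`"diameter"` or `"derivative"`).
#' @return object of class `xcorr_result`: `lags` (list per frequency,
#'   seconds), `r` (list per frequency of channels x lags matrices),
#'   `peak_lag` and `peak_r` (channels x frequencies), `grid`, `step_s`.
#' @export
xcorr_lagged <- function(pupil, env, max_lag_s = 10, peak_range_s = 5,
                         min_overlap_s = 30, fs_pupil = NULL,
                         field = "diameter") {
  stopifnot(inherits(env, "envelope_stack"))
  nf <- nrow(env$grid)
  nch <- env$n_channels
  lags <- rmat <- vector("list", nf)
  peak_lag <- peak_r <- matrix(NaN, nch, nf)
  for (k in seq_len(nf)) {
    pe <- pupil_at_envelope(pupil, fs_pupil, env, k, field = field)
    step <- env$step_s[k]
    L <- floor(max_lag_s / step)
    min_n <- max(2L, ceiling(min_overlap_s / step))
    lag_s <- ((-L):L) * step
    rk <- matrix(NaN, nch, 2L * L + 1L)
    for (ch in seq_len(nch))
      rk[ch, ] <- pearson_xcorr(env$power[[k]][, ch], pe, L, min_n = min_n)
    lags[[k]] <- lag_s
    rmat[[k]] <- rk
    inpk <- abs(lag_s) <= peak_range_s + 1e-9
    for (ch in seq_len(nch)) {
      rr <- rk[ch, ]
      rr[!inpk] <- NA
      if (all(is.na(rr))) next
      i0 <- which.max(abs(rr))
      peak_lag[ch, k] <- lag_s[i0]
      peak_r[ch, k] <- rr[i0]
    }
  }
  out <- list(lags = lags, r = rmat, peak_lag = peak_lag, peak_r = peak_r,
              grid = env$grid, step_s = env$step_s)
  class(out) <- "xcorr_result"
  out
}

#' Average cross-correlograms over frequency bands and spatial bins
#'
#' Channels are sorted from anterior to posterior by their coordinate and
#' split into `n_bins` equal-count, non-overlapping bins (any remainder is
#' assigned to the most posterior bins). Within each requested band, each
#' center frequency's correlogram is linearly interpolated onto the lag grid
#' of the band's highest center frequency, then averaged over frequencies
#' and over the channels of each bin.
#'
#' @param xc an `xcorr_result`.
#' @param coords anterior-posterior coordinate per channel (larger =
#'   more anterior).
#' @param bands list of length-2 band limits in Hz (defaults to 2-4, 8-16
#'   and 64-128 Hz).
#' @param n_bins number of spatial bins (default 39).
#' @return list of class `binned_xcorr`: per band, `lags` (s) and `r`
#'   (bins x lags); plus `bin_channels` (list of channel indices per bin,
#'   anterior first).
#' @export
bin_and_average_xcorr <- function(xc, coords,
                                  bands = list(c(2, 4), c(8, 16),
                                               c(64, 128)),
                                  n_bins = 39) {
  stopifnot(inherits(xc, "xcorr_result"))
  nch <- nrow(xc$peak_lag)
  stopifnot(length(coords) == nch, n_bins <= nch)
  ord <- order(coords, decreasing = TRUE)          # anterior first
  base <- nch %/% n_bins
  rem <- nch %% n_bins
  counts <- c(rep(base, n_bins - rem), rep(base + 1L, rem))
  if (rem) message(rem, " remainder channel(s) assigned to posterior bins")
  stops <- cumsum(counts)
  bin_channels <- lapply(seq_len(n_bins), function(b)
    ord[(stops[b] - counts[b] + 1L):stops[b]])

  out_bands <- vector("list", length(bands))
  for (bi in seq_along(bands)) {
    ks <- grid_band_idx(xc$grid, bands[[bi]])
    if (!length(ks)) stop("no grid centers in band ",
                          paste(bands[[bi]], collapse = "-"))
    kref <- ks[which.max(xc$grid$center[ks])]
    ref_lags <- xc$lags[[kref]]
    acc <- matrix(0, nch, length(ref_lags))
    for (k in ks) {
      if (k == kref) {
        acc <- acc + xc$r[[k]]
      } else {
        for (ch in seq_len(nch))
          acc[ch, ] <- acc[ch, ] +
            stats::approx(xc$lags[[k]], xc$r[[k]][ch, ], xout = ref_lags,
                          rule = 2)$y
      }
    }
    acc <- acc / length(ks)
    binned <- t(vapply(bin_channels, function(idx)
      colMeans(acc[idx, , drop = FALSE]), numeric(length(ref_lags))))
    out_bands[[bi]] <- list(band = bands[[bi]], lags = ref_lags, r = binned)
  }
  out <- list(bands = out_bands, bin_channels = bin_channels,
              n_bins = n_bins)
  class(out) <- "binned_xcorr"
  out
}

#' Extremum lag of band-averaged cross-correlograms
#'
#' Estimates the peak (signed-extremum) lag of each band's averaged
#' cross-correlogram from [bin_and_average_xcorr()]. Before peak-picking
#' the correlogram is smoothed with a short Gaussian kernel (default
#' 0.08 s): since the pupil signal is band-limited to 2 Hz, correlogram
#' structure finer than half that band's resolution cannot reflect
#' coupling and is envelope noise; smoothing at this scale removes the
#' noise-driven argmax jitter without biasing the (much broader) peak.
#'
#' @param bx a `binned_xcorr`.
#' @param smooth_s Gaussian smoothing SD in seconds (0 disables).
#' @param range_s lag range searched for the extremum (s, default 5).
#' @return data frame with one row per band x spatial bin: `band_lo`,
#'   `band_hi`, `bin`, `peak_lag` (s), `peak_r`.
#' @export
binned_peak_lag <- function(bx, smooth_s = 0.08, range_s = 5) {
  stopifnot(inherits(bx, "binned_xcorr"))
  out <- NULL
  for (bb in bx$bands) {
    dt <- bb$lags[2] - bb$lags[1]
    for (b in seq_len(nrow(bb$r))) {
      r <- bb$r[b, ]
      if (smooth_s > dt / 2) {
        hw <- ceiling(3 * smooth_s / dt)
        kk <- stats::dnorm((-hw:hw) * dt, sd = smooth_s)
        r <- stats::filter(r, kk / sum(kk), sides = 2)
      }
      sel <- abs(bb$lags) <= range_s + 1e-9 & !is.na(r)
      i0 <- which.max(abs(r) * sel)
      out <- rbind(out, data.frame(
        band_lo = bb$band[1], band_hi = bb$band[2], bin = b,
        peak_lag = bb$lags[i0], peak_r = r[i0]))
    }
  }
  out
}

## pair power(t) with pupil(t + k * step); k in envelope samples
align_at_lag <- function(power, pe, k) {
  n <- length(pe)
  if (k >= 0) list(x = power[seq_len(n - k)], y = pe[(1 + k):n])
  else list(x = power[(1 - k):n], y = pe[seq_len(n + k)])
}

#' Forward-shifted Spearman correlation map
#'
#' Spearman rank correlation of each channel x frequency power envelope with
#' the pupil series evaluated `shift_s` seconds later (`shift_s = 0.93` by
#' default, the canonical neuro-pupil lag; use `shift_s = 0` with
#' `field = "derivative"` for the pupil derivative). The shift is realized
#' as the nearest integer number of envelope samples at each frequency.
#'
#' @param pupil a `pupil_trace` or numeric vector (`fs_pupil` required).
#' @param env an `envelope_stack`.
#' @param shift_s forward shift of the pupil series (s).
#' @param fs_pupil sampling rate when `pupil` is a vector.
#' @param field pupil field (`"diameter"` or `"derivative"`).
#' @return object of class `rho_map`: `rho` (channels x frequencies),
#'   `shift_s`, `shift_samples` (per frequency), `grid`.
#' @export
shifted_rho_map <- function(pupil, env, shift_s = 0.93, fs_pupil = NULL,
                            field = "diameter") {
  stopifnot(inherits(env, "envelope_stack"))
  nf <- nrow(env$grid)
  nch <- env$n_channels
  rho <- matrix(NaN, nch, nf)
  shift_n <- integer(nf)
  for (k in seq_len(nf)) {
    pe <- pupil_at_envelope(pupil, fs_pupil, env, k, field = field)
    kk <- as.integer(round(shift_s / env$step_s[k]))
    shift_n[k] <- kk
    for (ch in seq_len(nch)) {
      al <- align_at_lag(env$power[[k]][, ch], pe, kk)
      rho[ch, k] <- stats::cor(al$x, al$y, method = "spearman")
    }
  }
  out <- list(rho = rho, shift_s = shift_s, shift_samples = shift_n,
              grid = env$grid)
  class(out) <- "rho_map"
  out
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf(
    "<mi_result> %d channels x %d frequencies, %d surrogates (guard %g s)\n",
    nrow(x$mi_z), ncol(x$mi_z), x$n_perm, x$guard_s))
  cat(sprintf("  mean z = %.2f, max |z| = %.2f\n",
              mean(x$mi_z, na.rm = TRUE), max(abs(x$mi_z), na.rm = TRUE)))
  invisible(x)
}

#' @export
print.xcorr_result <- function(x, ...) {
  cat(sprintf("<xcorr_result> %d channels x %d frequencies\n",
              nrow(x$peak_lag), ncol(x$peak_lag)))
  cat(sprintf("  median peak lag %.2f s, median peak r %.3f\n",
              stats::median(x$peak_lag, na.rm = TRUE),
              stats::median(x$peak_r, na.rm = TRUE)))
  invisible(x)
}
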