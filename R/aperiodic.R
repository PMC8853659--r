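## Spectral parameterization: aperiodic (offset + exponent) component plus
## up to six Gaussian periodic peaks, fitted iteratively in log10 power.

gaussian_sum <- function(f, peaks) {
  if (!nrow(peaks)) return(numeric(length(f)))
  g <- numeric(length(f))
  for (j in seq_len(nrow(peaks)))
    g <- g + peaks$height[j] *
      exp(-(f - peaks$center[j])^2 / (2 * peaks$sigma[j]^2))
  g
}

#' Parameterize a power spectrum into aperiodic and periodic components
#'
#' Iteratively fits `log10 psd` as the sum of an aperiodic component
#' `L(f) = offset - exponent * log10(f)` (knee fixed at zero) and up to
#' `max_peaks` Gaussians. Algorithm: (1) seed the aperiodic component by
#' least squares of log power on log frequency; (2) robust refit using only
#' points whose positive residual lies below the 2.5th-percentile threshold
#' (excluding points above the curve, i.e. peaks); (3) iteratively extract
#' Gaussians from the flattened spectrum, largest residual first, stopping
#' when the candidate height falls below `max(min_height,
#' peak_threshold * SD(flattened))`; (4) jointly refine all Gaussian
#' parameters by bounded least squares; (5) refit the aperiodic component on
#' the peak-subtracted spectrum.
#'
#' @param psd power spectral density (positive on the fit range).
#' @param freq frequency axis (Hz), same length.
#' @param fit_range frequency range used for fitting (Hz).
#' @param max_peaks maximum number of Gaussian peaks (default 6).
#' @param min_height minimum absolute peak height, log10 units (default 0.05).
#' @param peak_threshold relative detection threshold in SD of the flattened
#'   spectrum (default 2).
#' @param width_bounds bounds on the peak width, defined as `2 * sigma` of
#'   the Gaussian (Hz; default `c(1, 8)`).
#' @return object of class `aperiodic_fit`: `offset`, `exponent`, `peaks`
#'   (data frame: center, height, sigma, width), `freq`, `log_psd`,
#'   `aperiodic` (fitted log10 curve), `residual` (log10 psd minus aperiodic
#'   curve), `r_squared`, `converged`.
#' @examples
#' f <- seq(3, 40, by = 0.5)
#' fit <- fit_spectrum(10 * f^-2, f)
#' fit$exponent  # 2
#' @export
fit_spectrum <- function(psd, freq, fit_range = c(3, 40), max_peaks = 6,
                         min_height = 0.05, peak_threshold = 2,
                         width_bounds = c(1, 8)) {
  sel <- freq >= fit_range[1] - 1e-9 & freq <= fit_range[2] + 1e-9
  f <- freq[sel]
  p <- psd[sel]
  if (any(!is.finite(p)) || any(p <= 0))
    stop("psd must be finite and positive on the fit range")
  y <- log10(p)
  lf <- log10(f)
  sig_lo <- width_bounds[1] / 2
  sig_hi <- width_bounds[2] / 2

  ap_ols <- function(yy, keep = rep(TRUE, length(yy))) {
    cf <- stats::lm.fit(cbind(1, lf[keep]), yy[keep])$coefficients
    c(offset = cf[[1]], exponent = -cf[[2]])
  }
  ap_curve <- function(ap) ap[1] - ap[2] * lf

  fit_failed <- FALSE
  res <- tryCatch({
    ## (1) seed + (2) robust aperiodic fit
    ap <- ap_ols(y)
    resid0 <- pmax(y - ap_curve(ap), 0)
    thr <- stats::quantile(resid0, 0.025, names = FALSE)
    ap <- ap_ols(y, keep = resid0 <= thr)

    ## (3) iterative peak extraction from the flattened spectrum
    flat0 <- y - ap_curve(ap)
    flat <- flat0
    guesses <- data.frame(center = numeric(), height = numeric(),
                          sigma = numeric())
    for (it in seq_len(max_peaks)) {
      i0 <- which.max(flat)
      h <- flat[i0]
      if (h < max(min_height, peak_threshold * stats::sd(flat))) break
      ## width from half-height crossings
      li <- i0; while (li > 1 && flat[li] > h / 2) li <- li - 1
      ri <- i0; while (ri < length(f) && flat[ri] > h / 2) ri <- ri + 1
      fwhm <- max(f[ri] - f[li], diff(range(f)) / length(f))
      sg <- min(max(fwhm / 2.355, sig_lo), sig_hi)
      guesses <- rbind(guesses,
                       data.frame(center = f[i0], height = h, sigma = sg))
      flat <- flat - h * exp(-(f - f[i0])^2 / (2 * sg^2))
    }

    ## (4) joint bounded refinement of all Gaussians
    if (nrow(guesses)) {
      par0 <- as.numeric(t(as.matrix(guesses)))
      lo <- rep(c(fit_range[1], 0, sig_lo), nrow(guesses))
      hi <- rep(c(fit_range[2], Inf, sig_hi), nrow(guesses))
      ## centers constrained near their seeds (within two seed widths)
      for (j in seq_len(nrow(guesses))) {
        lo[3 * j - 2] <- max(fit_range[1],
                             guesses$center[j] - 2 * guesses$sigma[j])
        hi[3 * j - 2] <- min(fit_range[2],
                             guesses$center[j] + 2 * guesses$sigma[j])
      }
      obj <- function(par) {
        pk <- matrix(par, ncol = 3, byrow = TRUE)
        g <- numeric(length(f))
        for (j in seq_len(nrow(pk)))
          g <- g + pk[j, 2] * exp(-(f - pk[j, 1])^2 / (2 * pk[j, 3]^2))
        sum((flat0 - g)^2)
      }
      opt <- stats::optim(par0, obj, method = "L-BFGS-B", lower = lo,
                          upper = hi, control = list(maxit = 100))
      pk <- matrix(opt$par, ncol = 3, byrow = TRUE)
      guesses <- data.frame(center = pk[, 1], height = pk[, 2],
                            sigma = pk[, 3])
      guesses <- guesses[guesses$height >= min_height, , drop = FALSE]
    }

    ## (5) refit aperiodic on the peak-subtracted spectrum
    ap <- ap_ols(y - gaussian_sum(f, guesses))
    list(ap = ap, peaks = guesses)
  }, error = function(e) {
    fit_failed <<- TRUE
    list(ap = c(offset = NaN, exponent = NaN),
         peaks = data.frame(center = numeric(), height = numeric(),
                            sigma = numeric()))
  })

  ap <- res$ap
  peaks <- res$peaks
  curve <- ap[1] - ap[2] * lf
  model <- curve + gaussian_sum(f, peaks)
  r2 <- if (fit_failed) NaN else
    1 - sum((y - model)^2) / max(sum((y - mean(y))^2), 1e-300)
  peaks$width <- 2 * peaks$sigma
  out <- list(offset = unname(ap[1]), exponent = unname(ap[2]),
              peaks = peaks, freq = f, log_psd = y, aperiodic = curve,
              residual = y - curve, r_squared = r2,
              fit_range = fit_range, converged = !fit_failed)
  class(out) <- "aperiodic_fit"
  out
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf(
    "<aperiodic_fit> offset %.3f, exponent %.3f, %d peak(s), R^2 %.3f\n",
    x$offset, x$exponent, nrow(x$peaks), x$r_squared))
  if (nrow(x$peaks))
    print(format(x$peaks, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Per-segment spectral exponents and their coupling with pupil state
#'
#' Applies [fit_spectrum()] to every segment of a [segment_spectra()] result
#' and returns the exponent time series aligned with the per-segment pupil
#' values, the correlation between exponent and pupil, and the 14-bin
#' mean-exponent-by-pupil curve.
#'
#' @param seg a `segmented_spectra`.
#' @param channel channel index.
#' @param fit_range,max_peaks,min_height,peak_threshold,width_bounds passed
#'   to [fit_spectrum()].
#' @param method correlation method, `"pearson"` (default) or `"spearman"`.
#' @param n_bins bins for the exponent-by-pupil curve (default 14).
#' @return list with `exponent` (per segment), `seg_pupil`,
#'   `seg_pupil_deriv`, `fits` (list of `aperiodic_fit`), `r_pupil`
#'   (correlation, 0 when either series is constant), `binned`
#'   (a `binned_curve` of exponent by pupil, unstandardized).
#' @export
exponent_series <- function(seg, channel = 1, fit_range = c(3, 40),
                            max_peaks = 6, min_height = 0.05,
                            peak_threshold = 2, width_bounds = c(1, 8),
                            method = c("pearson", "spearman"),
                            n_bins = 14) {
  method <- match.arg(method)
  stopifnot(inherits(seg, "segmented_spectra"))
  ns <- length(seg$seg_t)
  if (ns < 14) stop("need at least 14 segments")
  fits <- vector("list", ns)
  expo <- numeric(ns)
  for (i in seq_len(ns)) {
    fits[[i]] <- fit_spectrum(seg$psd[[channel]][i, ], seg$freq,
                              fit_range = fit_range, max_peaks = max_peaks,
                              min_height = min_height,
                              peak_threshold = peak_threshold,
                              width_bounds = width_bounds)
    expo[i] <- fits[[i]]$exponent
  }
  bad <- !is.finite(expo)
  if (mean(bad) > 0.2) stop("more than 20% of segment fits failed")
  ok <- !bad
  r <- if (stats::sd(expo[ok]) == 0 || stats::sd(seg$seg_pupil[ok]) == 0) 0
       else stats::cor(expo[ok], seg$seg_pupil[ok], method = method)
  binned <- bin_by_pupil(expo[ok], seg$seg_pupil[ok], n_bins = n_bins,
                         standardize = FALSE)
  list(exponent = expo, seg_pupil = seg$seg_pupil,
       seg_pupil_deriv = seg$seg_pupil_deriv, fits = fits,
       r_pupil = r, binned = binned)
}

#' Residualized band power after removing the aperiodic component
#'
#' Subtracts each segment's fitted aperiodic curve from its log10 power
#' spectrum and averages the residual over each half-octave band of the
#' wavelet grid whose center lies inside the fit range. Correlating the
#' result with per-segment pupil values isolates periodic (oscillatory)
#' coupling from aperiodic-exponent coupling.
#'
#' @param seg a `segmented_spectra`.
#' @param fits list of per-segment `aperiodic_fit`s (e.g. from
#'   [exponent_series()]), same channel.
#' @param grid a [freq_grid()].
#' @return list with `residual_power` (segments x centers, log10 units),
#'   `centers` (Hz), `r_pupil` (per-center correlation with `seg$seg_pupil`).
#' @export
residual_band_power <- function(seg, fits, grid = freq_grid()) {
  stopifnot(inherits(seg, "segmented_spectra"))
  fr <- fits[[which(vapply(fits, function(f) f$converged, logical(1)))[1]]]
  rng <- fr$fit_range
  ks <- which(grid$center >= rng[1] & grid$center <= rng[2])
  if (!all(grid$band_lo[ks] >= rng[1] & grid$band_hi[ks] <= rng[2]))
    message("bands extending beyond the fit range were clipped to it")
  ns <- length(seg$seg_t)
  rp <- matrix(NaN, ns, length(ks))
  f <- fr$freq
  for (i in seq_len(ns)) {
    if (!fits[[i]]$converged) next
    resid <- fits[[i]]$residual
    for (j in seq_along(ks)) {
      k <- ks[j]
      selb <- f >= max(grid$band_lo[k], rng[1]) &
        f <= min(grid$band_hi[k], rng[2])
      rp[i, j] <- mean(resid[selb])
    }
  }
  ok <- is.finite(rp[, 1])
  r <- apply(rp[ok, , drop = FALSE], 2, function(v)
    if (stats::sd(v) == 0) 0 else stats::cor(v, seg$seg_pupil[ok]))
  list(residual_power = rp, centers = grid$center[ks], r_pupil = r)
}
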