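#' Logarithmic wavelet frequency grid (2-128 Hz)
#'
#' Builds the analysis grid of 25 logarithmically spaced center frequencies,
#' `f_k = 2 * 2^(k/4)` for k = 0..24, each with a half-octave band
#' `[f * 2^(-1/4), f * 2^(1/4)]`. The spectral width of the Morlet wavelet at
#' each center is `sigma_f = (band_hi - band_lo) / 2`, so that one standard
#' deviation of its Gaussian spectral profile spans the band; the temporal
#' width is `sigma_t = 1 / (2 * pi * sigma_f)`. Successive analysis windows
#' overlap by 80% of the wavelet support (`+/- 3 sigma_t`), giving a
#' per-frequency envelope sampling step of `1.2 * sigma_t`.
#'
#' @param n_freqs number of centers (default 25).
#' @param f_min lowest center frequency in Hz (default 2).
#' @param overlap fractional window overlap (default 0.8).
#' @return data frame of class `freq_grid` with columns `center`, `band_lo`,
#'   `band_hi`, `sigma_f`, `sigma_t`, `window_s` (support `6 sigma_t`) and
#'   `step_s` (envelope sampling step in seconds).
#' @examples
#' g <- freq_grid()
#' range(g$center)   # 2 ... 128 Hz
#' @export
freq_grid <- function(n_freqs = 25, f_min = 2, overlap = 0.8) {
  stopifnot(n_freqs >= 1, f_min > 0, overlap >= 0, overlap < 1)
  k <- seq_len(n_freqs) - 1
  centers <- f_min * 2^(k / 4)
  band_lo <- centers * 2^(-1 / 4)
  band_hi <- centers * 2^(1 / 4)
  sigma_f <- (band_hi - band_lo) / 2
  sigma_t <- 1 / (2 * pi * sigma_f)
  window_s <- 6 * sigma_t
  g <- data.frame(
    center = centers, band_lo = band_lo, band_hi = band_hi,
    sigma_f = sigma_f, sigma_t = sigma_t,
    window_s = window_s, step_s = (1 - overlap) * window_s
  )
  class(g) <- c("freq_grid", "data.frame")
  g
}

#' Indices of grid centers falling inside a frequency band
#' @param grid a [freq_grid()].
#' @param band numeric length-2, band limits in Hz (inclusive).
#' @export
grid_band_idx <- function(grid, band) {
  which(grid$center >= band[1] - 1e-9 & grid$center <= band[2] + 1e-9)
}
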