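## Microsaccade detection from gaze velocity and event-locked spectral
## power / pupil changes (control analysis).

#' Detect microsaccades from gaze traces
#'
#' Velocity-threshold detection: gaze velocities are computed with a 5-point
#' moving-window derivative, a median-based noise scale
#' `eta = sqrt(median(v^2) - median(v)^2)` is estimated per axis, and a
#' microsaccade is a run of at least `min_dur_samples` samples for which
#' `(vx / (lambda eta_x))^2 + (vy / (lambda eta_y))^2 > 1`. Candidate events
#' separated by less than `merge_gap_s` are merged.
#'
#' @param gaze_xy two-column matrix (x, y) of gaze positions, gap-free.
#' @param fs sampling rate (Hz).
#' @param lambda velocity threshold multiplier (default 6).
#' @param min_dur_samples minimum event duration in samples (default 5).
#' @param merge_gap_s merge events closer than this (s, default 0.02).
#' @return object of class `microsaccades`: data frame with `onset`
#'   (seconds), `duration` (s), `peak_velocity`, `amplitude` (displacement).
#'   Zero rows when gaze is constant (noise scale zero).
#' @export
detect_microsaccades <- function(gaze_xy, fs, lambda = 6,
                                 min_dur_samples = 5, merge_gap_s = 0.02) {
  gaze_xy <- as.matrix(gaze_xy)
  stopifnot(ncol(gaze_xy) == 2, all(is.finite(gaze_xy)))
  n <- nrow(gaze_xy)
  vel <- function(x) {
    v <- numeric(n)
    v[3:(n - 2)] <- (x[5:n] + x[4:(n - 1)] - x[2:(n - 3)] - x[1:(n - 4)]) *
      fs / 6
    v
  }
  vx <- vel(gaze_xy[, 1])
  vy <- vel(gaze_xy[, 2])
  eta <- function(v) sqrt(stats::median(v^2) - stats::median(v)^2)
  ex <- eta(vx)
  ey <- eta(vy)
  empty <- data.frame(onset = numeric(), duration = numeric(),
                      peak_velocity = numeric(), amplitude = numeric())
  if (ex == 0 || ey == 0 || !is.finite(ex) || !is.finite(ey)) {
    message("constant gaze; no events detectable")
    out <- empty
    class(out) <- c("microsaccades", "data.frame")
    return(out)
  }
  crit <- (vx / (lambda * ex))^2 + (vy / (lambda * ey))^2 > 1
  r <- rle(crit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(ev)) {                 # merge close events, then length-filter
    merged <- ev[1, , drop = FALSE]
    if (nrow(ev) > 1) for (i in 2:nrow(ev)) {
      if (ev$start[i] - merged$end[nrow(merged)] < merge_gap_s * fs)
        merged$end[nrow(merged)] <- ev$end[i]
      else merged <- rbind(merged, ev[i, ])
    }
    ev <- merged[merged$end - merged$start + 1L >= min_dur_samples, ,
                 drop = FALSE]
  }
  if (!nrow(ev)) {
    out <- empty
  } else {
    out <- data.frame(
      onset = (ev$start - 1) / fs,
      duration = (ev$end - ev$start + 1) / fs,
      peak_velocity = vapply(seq_len(nrow(ev)), function(i)
        max(sqrt(vx[ev$start[i]:ev$end[i]]^2 +
                   vy[ev$start[i]:ev$end[i]]^2)), numeric(1)),
      amplitude = vapply(seq_len(nrow(ev)), function(i)
        sqrt((gaze_xy[ev$end[i], 1] - gaze_xy[ev$start[i], 1])^2 +
               (gaze_xy[ev$end[i], 2] - gaze_xy[ev$start[i], 2])^2),
        numeric(1)))
  }
  class(out) <- c("microsaccades", "data.frame")
  out
}

#' Event-locked percent change in spectral power and pupil size
#'
#' Around each event onset, spectral power is estimated in sliding
#' Hann-tapered windows (0.5 s length, 50 ms step by default) spanning
#' `t_range`; power is averaged over events and expressed as percent change
#' relative to the pre-event baseline bin (the bin centered at -0.25 s).
#' Pupil size per bin is the Hann-tapered windowed sum, with percent change
#' computed identically.
#'
#' @param x neural time series (vector or time x channels matrix).
#' @param fs sampling rate (Hz).
#' @param events event onset times (seconds).
#' @param window_s sliding window length (s, default 0.5).
#' @param step_s window step (s, default 0.05).
#' @param t_range peri-event range (s, default `c(-0.5, 2)`).
#' @param pupil optional pupil vector on the same time grid.
#' @return object of class `event_locked`: `t_bins` (bin centers, s),
#'   `freq` (Hz), `pct_power` (bins x freqs, averaged over channels),
#'   `pct_pupil` (or `NULL`), `n_events`, `n_dropped`.
#' @export
event_locked_power <- function(x, fs, events, window_s = 0.5,
                               step_s = 0.05, t_range = c(-0.5, 2),
                               pupil = NULL) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  wn <- round(window_s * fs)
  centers <- seq(t_range[1] + window_s / 2, t_range[2] - window_s / 2,
                 by = step_s)
  ok <- vapply(events, function(e) {
    i0 <- round((e + centers[1] - window_s / 2) * fs) + 1L
    i1 <- round((e + centers[length(centers)] + window_s / 2) * fs)
    i0 >= 1 && i1 <= n
  }, logical(1))
  n_dropped <- sum(!ok)
  events <- events[ok]
  if (length(events) < 10)
    stop("fewer than 10 events with full peri-event coverage")
  nf <- wn %/% 2 + 1
  w <- hann_window(wn)
  acc_p <- matrix(0, length(centers), nf)
  acc_pupil <- numeric(length(centers))
  for (e in events) {
    for (b in seq_along(centers)) {
      i0 <- round((e + centers[b] - window_s / 2) * fs) + 1L
      idx <- i0:(i0 + wn - 1L)
      for (ch in seq_len(ncol(x)))
        acc_p[b, ] <- acc_p[b, ] + welch_segment_psd(x[idx, ch], fs)$psd
      if (!is.null(pupil))
        acc_pupil[b] <- acc_pupil[b] + sum(pupil[idx] * w)
    }
  }
  acc_p <- acc_p / (length(events) * ncol(x))
  base_bin <- which.min(abs(centers + 0.25))
  pct_power <- 100 * sweep(sweep(acc_p, 2, acc_p[base_bin, ], "-"),
                           2, acc_p[base_bin, ], "/")
  pct_pupil <- NULL
  if (!is.null(pupil)) {
    acc_pupil <- acc_pupil / length(events)
    pct_pupil <- 100 * (acc_pupil - acc_pupil[base_bin]) /
      acc_pupil[base_bin]
  }
  out <- list(t_bins = centers, freq = fs * (0:(nf - 1)) / wn,
              pct_power = pct_power, pct_pupil = pct_pupil,
              n_events = length(events), n_dropped = n_dropped)
  class(out) <- "event_locked"
  out
}
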