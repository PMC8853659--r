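## Binned quadratic (inverted-U) modeling of power or exponent as a
## function of pupil state: P = b0 + b1 x + b2 x^2, with b2 < 0 indicating
## an inverted-U over the fitted range.

#' Bin segment values by pupil state
#'
#' Sorts segments into `n_bins` non-overlapping, equidistant pupil bins
#' spanning `[min, max]` of the per-segment pupil values, averages the
#' segment values within each bin, and (by default) z-scores the bin means.
#' Bin centers are the mean pupil value of the members. Empty bins yield
#' `NaN` and are excluded from subsequent fitting; more than 4 empty bins is
#' an error.
#'
#' @param seg_values per-segment values (power, exponent, ...).
#' @param seg_pupil per-segment pupil values (non-constant).
#' @param n_bins number of bins (default 14).
#' @param standardize z-score the bin means across bins (default `TRUE`).
#' @return object of class `binned_curve`: `bin_centers`, `bin_means`,
#'   `bin_counts`, `edges`; attribute `degenerate` is `TRUE` when the values
#'   have zero variance (fit should be skipped).
#' @export
bin_by_pupil <- function(seg_values, seg_pupil, n_bins = 14,
                         standardize = TRUE) {
  stopifnot(length(seg_values) == length(seg_pupil))
  if (length(seg_values) < n_bins)
    stop("need at least ", n_bins, " segments")
  if (stats::sd(seg_pupil) == 0) stop("pupil values are constant")
  edges <- seq(min(seg_pupil), max(seg_pupil), length.out = n_bins + 1)
  idx <- findInterval(seg_pupil, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  means <- centers <- rep(NaN, n_bins)
  counts <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    sel <- idx == b
    counts[b] <- sum(sel)
    if (counts[b]) {
      means[b] <- mean(seg_values[sel])
      centers[b] <- mean(seg_pupil[sel])
    }
  }
  n_empty <- sum(counts == 0)
  if (n_empty > 4) stop(n_empty, " empty pupil bins; binning unusable")
  if (n_empty > 0) message(n_empty, " empty pupil bin(s) excluded")
  degenerate <- FALSE
  if (standardize) {
    ok <- is.finite(means)
    s <- stats::sd(means[ok])
    if (!is.finite(s) || s == 0) {
      degenerate <- TRUE
    } else {
      means[ok] <- (means[ok] - mean(means[ok])) / s
    }
  }
  out <- list(bin_centers = centers, bin_means = means, bin_counts = counts,
              edges = edges, standardized = standardize)
  class(out) <- "binned_curve"
  attr(out, "degenerate") <- degenerate
  out
}

#' @export
print.binned_curve <- function(x, ...) {
  cat(sprintf("<binned_curve> %d bins (%d occupied)%s\n",
              length(x$bin_means), sum(is.finite(x$bin_means)),
              if (isTRUE(attr(x, "degenerate"))) " [degenerate]" else ""))
  invisible(x)
}

#' @export
plot.binned_curve <- function(x, ...) {
  plot(x$bin_centers, x$bin_means, type = "b", pch = 16,
       xlab = "pupil (bin mean)",
       ylab = if (x$standardized) "value (z)" else "value", ...)
  invisible(x)
}

#' Quadratic fit of a binned pupil curve
#'
#' Least-squares fit of `P = b0 + b1 x + b2 x^2` to the bin means, where
#' `x` is the z-scored bin centers (making coefficients comparable across
#' subjects regardless of raw pupil units). `b2 < 0` indicates an inverted-U
#' relation over the fitted range.
#'
#' @param curve a [bin_by_pupil()] result.
#' @param min_valid_bins minimum occupied bins required (default 10).
#' @return object of class `quad_fit`: `beta0`, `beta1`, `beta2`, `sse`.
#' @export
fit_quadratic <- function(curve, min_valid_bins = 10) {
  stopifnot(inherits(curve, "binned_curve"))
  if (isTRUE(attr(curve, "degenerate")))
    stop("degenerate curve (constant values); fit skipped")
  ok <- is.finite(curve$bin_means) & is.finite(curve$bin_centers)
  if (sum(ok) < min_valid_bins)
    stop("fewer than ", min_valid_bins, " valid bins")
  x <- curve$bin_centers[ok]
  if (length(unique(x)) <= 3) stop("rank-deficient design (<= 3 distinct x)")
  x <- (x - mean(x)) / stats::sd(x)
  y <- curve$bin_means[ok]
  fit <- stats::lm.fit(cbind(1, x, x^2), y)
  out <- list(beta0 = unname(fit$coefficients[1]),
              beta1 = unname(fit$coefficients[2]),
              beta2 = unname(fit$coefficients[3]),
              sse = sum(fit$residuals^2))
  class(out) <- "quad_fit"
  out
}

#' @export
print.quad_fit <- function(x, ...) {
  cat(sprintf("<quad_fit> b0 = %.3f, b1 = %.3f, b2 = %.3f (%s), SSE %.3g\n",
              x$beta0, x$beta1, x$beta2,
              if (x$beta2 < 0) "inverted-U" else "U-shaped", x$sse))
  invisible(x)
}

#' Group-level map of quadratic coefficients
#'
#' For every subject and cell (channel x frequency, or any generic cell
#' layout), bins the per-segment values by pupil, fits the quadratic model,
#' collects the `beta2` coefficients, and tests them against zero across
#' subjects with a two-tailed one-sample t-test per cell, controlling the
#' false discovery rate across cells by Benjamini-Hochberg at level `q`.
#'
#' @param subjects list; each element is a list with `values` (segments x
#'   cells matrix) and `pupil` (per-segment pupil vector).
#' @param n_bins pupil bins (default 14).
#' @param q FDR level (default 0.1).
#' @param cell_names optional cell labels.
#' @return object of class `quad_map`: `beta2` (subjects x cells), `beta1`,
#'   `test` (a `group_test`), `cell_names`.
#' @export
quad_map <- function(subjects, n_bins = 14, q = 0.1, cell_names = NULL) {
  ncell <- ncol(subjects[[1]]$values)
  ns <- length(subjects)
  b2 <- b1 <- matrix(NaN, ns, ncell)
  for (s in seq_len(ns)) {
    sub <- subjects[[s]]
    for (j in seq_len(ncell)) {
      fit <- tryCatch(
        fit_quadratic(bin_by_pupil(sub$values[, j], sub$pupil,
                                   n_bins = n_bins)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        b2[s, j] <- fit$beta2
        b1[s, j] <- fit$beta1
      }
    }
  }
  test <- group_ttest_map(b2, q = q)
  out <- list(beta2 = b2, beta1 = b1, test = test,
              cell_names = cell_names %||% colnames(subjects[[1]]$values))
  class(out) <- "quad_map"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
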