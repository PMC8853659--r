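## Group-level inference: one-sample two-tailed t-tests against zero and
## Benjamini-Hochberg FDR control shared by all analyses.

#' One-sample two-tailed t-test against zero
#'
#' Group statistic for per-subject coupling values (standardized MI,
#' correlation coefficients, quadratic coefficients): a two-tailed
#' one-sample t-test of the subject values against zero.
#'
#' @param values numeric vector of per-subject values (n >= 3 finite).
#' @return list with `t`, `p`, `df`, `mean`, `se`.
#' @export
group_ttest <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 3) stop("need at least 3 finite values")
  if (stats::sd(v) == 0) stop("zero variance across subjects")
  n <- length(v)
  se <- stats::sd(v) / sqrt(n)
  tt <- mean(v) / se
  list(t = tt, p = 2 * stats::pt(-abs(tt), df = n - 1), df = n - 1,
       mean = mean(v), se = se)
}

#' Benjamini-Hochberg FDR threshold and rejection mask
#'
#' Step-up procedure: sort the p-values ascending and find the largest k
#' with `p(k) <= k * q / m`; `fdr_alpha` is that `p(k)` (0 when nothing is
#' rejected) and all `p <= fdr_alpha` are rejected.
#'
#' @param p p-values in `[0, 1]`.
#' @param q FDR level (default 0.1).
#' @return object of class `fdr_result`: `fdr_alpha`, `reject` (logical,
#'   `NA` p-values never rejected), `q`, `n_reject`.
#' @export
bh_fdr <- function(p, q = 0.1) {
  if (!length(p)) stop("empty p-value vector")
  ok <- is.finite(p)
  stopifnot(all(p[ok] >= 0 & p[ok] <= 1))
  ps <- sort(p[ok])
  m <- length(ps)
  k <- which(ps <= seq_len(m) * q / m)
  alpha <- if (length(k)) ps[max(k)] else 0
  reject <- ifelse(ok, p <= alpha & alpha > 0, FALSE)
  out <- list(fdr_alpha = alpha, reject = reject, q = q,
              n_reject = sum(reject))
  class(out) <- "fdr_result"
  out
}

#' Cell-wise group t-tests with FDR control
#'
#' Applies [group_ttest()] to every column of a subjects x cells matrix and
#' controls the FDR across cells at level `q` (the FDR family is one
#' analysis map, e.g. all channel x frequency cells of one measure).
#'
#' @param values subjects x cells matrix.
#' @param q FDR level (default 0.1).
#' @return object of class `group_test`: `t`, `p`, `mean`, `se` per cell,
#'   `df`, `fdr_alpha`, `reject`, `q`.
#' @export
group_ttest_map <- function(values, q = 0.1) {
  values <- as.matrix(values)
  ncell <- ncol(values)
  t_ <- p_ <- m_ <- se_ <- rep(NaN, ncell)
  df <- NA_integer_
  for (j in seq_len(ncell)) {
    res <- tryCatch(group_ttest(values[, j]), error = function(e) NULL)
    if (!is.null(res)) {
      t_[j] <- res$t; p_[j] <- res$p; m_[j] <- res$mean; se_[j] <- res$se
      df <- res$df
    }
  }
  fdr <- bh_fdr(p_, q = q)
  out <- list(t = t_, p = p_, mean = m_, se = se_, df = df,
              fdr_alpha = fdr$fdr_alpha, reject = fdr$reject, q = q)
  class(out) <- "group_test"
  out
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf(
    "<group_test> %d cells, df = %s, FDR q = %g -> alpha = %.4g (%d sig.)\n",
    length(x$p), format(x$df), x$q, x$fdr_alpha, sum(x$reject, na.rm = TRUE)))
  invisible(x)
}
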