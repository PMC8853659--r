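# Binned quadratic (inverted-U) pupil-power model.

test_that("pupil binning uses equidistant edges and z-scored means", {
  set.seed(1)
  pupil <- runif(500)
  curve <- bin_by_pupil(pupil, pupil)          # values = pupil itself
  # equidistant edges over [min, max]
  expect_equal(diff(curve$edges), rep(diff(range(pupil)) / 14, 14))
  # monotone values stay monotone after binning
  expect_true(all(diff(curve$bin_means[is.finite(curve$bin_means)]) > 0))
  # z-scoring across bins
  ok <- is.finite(curve$bin_means)
  expect_equal(mean(curve$bin_means[ok]), 0, tolerance = 1e-12)
  expect_equal(sd(curve$bin_means[ok]), 1, tolerance = 1e-12)

  # constant values cannot be standardized: degenerate flag, fit refuses
  dg <- bin_by_pupil(rep(2, 500), pupil)
  expect_true(attr(dg, "degenerate"))
  expect_error(fit_quadratic(dg), "degenerate")

  expect_error(bin_by_pupil(pupil, rep(1, 500)), "constant")
})

test_that("quadratic fit recovers pure quadratic and pure linear shapes", {
  # curves whose bin means are exact functions of the (z-scored) centers
  make_curve <- function(centers, means) {
    out <- list(bin_centers = centers, bin_means = means,
                bin_counts = rep(10L, length(centers)),
                edges = seq(0, 1, length.out = length(centers) + 1),
                standardized = TRUE)
    class(out) <- "binned_curve"
    out
  }
  centers <- seq(-1, 1, length.out = 14)
  x <- (centers - mean(centers)) / sd(centers)
  # pure quadratic dependence: beta1 vanishes identically
  qf <- fit_quadratic(make_curve(centers, x^2))
  expect_gt(qf$beta2, 0)
  expect_lt(abs(qf$beta1), 1e-10)
  expect_lt(qf$sse, 1e-20)
  # pure linear dependence: beta2 vanishes identically
  lf <- fit_quadratic(make_curve(centers, 3 * x))
  expect_lt(abs(lf$beta2), 1e-10)
  expect_gt(lf$beta1, 0)
  # inverted-U
  uf <- fit_quadratic(make_curve(centers, -x^2))
  expect_lt(uf$beta2, 0)
  # binning a noisy inverted-U end to end keeps the sign
  set.seed(2)
  pupil <- runif(2000, -1, 1)
  ef <- fit_quadratic(bin_by_pupil(-(pupil^2) + rnorm(2000, sd = 0.05),
                                   pupil))
  expect_lt(ef$beta2, 0)
})

test_that("quadratic fit agrees with a normal-equations oracle", {
  set.seed(3)
  for (i in 1:10) {
    pupil <- rnorm(300)
    vals <- rnorm(300)
    curve <- bin_by_pupil(vals, pupil)
    qf <- tryCatch(fit_quadratic(curve), error = function(e) NULL)
    if (is.null(qf)) next
    ok <- is.finite(curve$bin_means)
    x <- curve$bin_centers[ok]
    x <- (x - mean(x)) / sd(x)
    X <- cbind(1, x, x^2)
    beta <- solve(t(X) %*% X, t(X) %*% curve$bin_means[ok])
    expect_equal(c(qf$beta0, qf$beta1, qf$beta2), as.numeric(beta),
                 tolerance = 1e-10)
  }
})

test_that("beta2 is invariant to affine rescaling of raw pupil units", {
  set.seed(4)
  pupil <- rnorm(400)
  vals <- -0.5 * pupil^2 + 0.2 * pupil + rnorm(400, sd = 0.1)
  f1 <- fit_quadratic(bin_by_pupil(vals, pupil))
  f2 <- fit_quadratic(bin_by_pupil(vals, 37 + 4.2 * pupil))
  expect_equal(f1$beta2, f2$beta2, tolerance = 1e-10)
})

test_that("pure linear coupling yields no systematic quadratic term", {
  set.seed(5)
  b2 <- replicate(50, {
    pupil <- rnorm(300)
    vals <- 0.8 * pupil + rnorm(300, sd = 0.5)
    fit_quadratic(bin_by_pupil(vals, pupil))$beta2
  })
  expect_lt(abs(mean(b2)), 2 * sd(b2) / sqrt(length(b2)))
})

test_that("binning interface applies to exponent series unchanged", {
  set.seed(6)
  pupil <- rnorm(200)
  expo <- 1.5 - 0.2 * pupil + rnorm(200, sd = 0.05)
  curve <- bin_by_pupil(expo, pupil, standardize = FALSE)
  ok <- is.finite(curve$bin_means)
  expect_true(all(diff(curve$bin_means[ok]) < 0.2))  # mostly decreasing
  expect_lt(cor(curve$bin_centers[ok], curve$bin_means[ok]), -0.9)
})
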