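test_that("decay histogram and model constructors enforce their invariants", {
  expect_error(decay_histogram(c(0, 1, 3), c(1, 1, 1)), "constant step")
  expect_error(decay_histogram(c(1, 2, 3), c(1, 1, 1)), "start at 0")
  expect_error(decay_histogram(c(0, 1, 2), c(1, -1, 1)), "non-negative")
  m <- multiexp_model(c(0.3, 0.7), c(1.7, 0.58))
  expect_equal(m$lifetimes, c(0.58, 1.7)) # sorted ascending
  expect_equal(sum(m$amplitudes), 1)
  expect_equal(m$amplitudes, c(0.7, 0.3))
  expect_error(multiexp_model(1, -2), "lifetimes")
})

test_that("reconvolution with a delta IRF reduces to the pure exponential", {
  irf <- delta_irf()
  y <- convolve_model(multiexp_model(1, 3.3), irf)
  expect_equal(y, exp(-irf$time / 3.3), tolerance = 1e-12)
})

test_that("Gaussian-IRF reconvolution matches the closed-form EMG to <0.1%", {
  fwhm <- 0.042
  mu <- 1
  irf <- make_irf(
    n_channels = 4096, window_ns = 20, fwhm_ns = fwhm,
    center_ns = mu, poisson = FALSE
  )
  y <- convolve_model(multiexp_model(1, 3.3), irf)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  # the discrete reconvolution samples both sequences at channel left edges,
  # which is equivalent to the continuous convolution evaluated half a
  # channel later; the fitted shift parameter absorbs this in practice
  dt <- irf$time[2] - irf$time[1]
  oracle <- emg_curve(irf$time + dt / 2, 3.3, mu, sigma)
  expect_lt(max(abs(y - oracle)) / max(oracle), 2e-3)
})

test_that("a near-infinite lifetime gives a flat curve at background + constant", {
  irf <- small_irf()
  m <- multiexp_model(1, 1e6, background = 7)
  y <- convolve_model(m, irf)
  tail_part <- y[irf$time > 3] # past the IRF rise
  expect_lt(diff(range(tail_part)), 1e-4 * mean(tail_part))
  expect_gt(min(tail_part), 7)
})

test_that("amplitude-weighted lifetime is the normalized amplitude mean", {
  expect_equal(amplitude_weighted_lifetime(c(0.70, 0.30), c(0.58, 1.7)), 0.916)
  expect_equal(amplitude_weighted_lifetime(1, 3.3), 3.3)
  expect_equal(amplitude_weighted_lifetime(c(0.5, 0.5), c(1, 3)), 2.0)
  # permutation invariance
  expect_equal(
    amplitude_weighted_lifetime(c(0.3, 0.7), c(1.7, 0.58)),
    amplitude_weighted_lifetime(c(0.7, 0.3), c(0.58, 1.7))
  )
  # via a model object
  expect_equal(
    amplitude_weighted_lifetime(multiexp_model(c(2, 8), c(1, 2))),
    1.8
  )
})

test_that("reduced chi-square behaves as a goodness-of-fit statistic", {
  expected <- 1000 * exp(-(0:499) / 100) + 5
  expect_equal(reduced_chi_square(expected, expected, 3), 0)
  # Poisson sample of the truth: chi2_red ~ 1 within 3 sigma of chi2 dist
  set.seed(42)
  obs <- rpois(length(expected), expected)
  chi2 <- reduced_chi_square(obs, expected, 0)
  expect_lt(abs(chi2 - 1), 3 * sqrt(2 / length(expected)))
  expect_error(reduced_chi_square(obs, expected * 0, 0), "usable")
})

test_that("fitting the wrong model inflates reduced chi-square", {
  irf <- small_irf()
  d <- make_decay(multiexp_model(c(0.7, 0.3), c(0.58, 1.7)), irf, seed = 11)
  fit1 <- fit_decay(d, irf, n_components = 1)
  expect_gt(fit1$chi2_reduced, 1.5)
  fit2 <- fit_decay(d, irf, n_components = 2)
  expect_lt(fit2$chi2_reduced, 1.3)
})

test_that("noiseless model curves are recovered to solver tolerance", {
  irf <- small_irf(seed = 5)
  truth <- multiexp_model(c(0.6, 0.4), c(0.8, 2.5))
  d <- make_decay(truth, irf, poisson = FALSE)
  fit <- fit_decay(d, irf, n_components = 2)
  expect_equal(fit$model$lifetimes, truth$lifetimes, tolerance = 1e-3)
  expect_equal(fit$model$amplitudes, truth$amplitudes, tolerance = 1e-3)
})

test_that("delta-IRF reconvolution fits agree with plain tail decay", {
  irf <- delta_irf()
  d <- make_decay(multiexp_model(1, 3.3), irf, seed = 21)
  # with a delta IRF the shift is unidentifiable, so the covariance is
  # flagged as degenerate; the point estimates are still well-defined
  expect_warning(
    fit <- fit_decay(d, irf, n_components = 1),
    "Degenerate covariance"
  )
  # direct log-linear estimate on noiseless-dominant early channels
  expect_equal(fit$model$lifetimes, 3.3, tolerance = 0.05)
  expect_true(fit$converged)
})

test_that("fit_decay is deterministic for fixed data", {
  irf <- small_irf(seed = 8)
  d <- make_decay(multiexp_model(1, 2), irf, seed = 9)
  f1 <- fit_decay(d, irf, 1)
  f2 <- fit_decay(d, irf, 1)
  expect_identical(tidy(f1), tidy(f2))
})

test_that("mono-exponential lifetime recovery is unbiased at acquisition counts", {
  # 10 seeds here; the acceptance suite runs the full 50-seed version
  irf <- small_irf(n_channels = 2048, window_ns = 40, seed = 1)
  taus <- vapply(1:10, function(s) {
    d <- make_decay(multiexp_model(1, 3.3), irf, seed = s)
    fit_decay(d, irf, 1)$model$lifetimes
  }, numeric(1))
  expect_lt(abs(mean(taus) - 3.3) / 3.3, 0.02)
})

test_that("tidy and glance expose the fit in broom form", {
  irf <- small_irf(seed = 2)
  d <- make_decay(multiexp_model(1, 2), irf, seed = 3)
  fit <- fit_decay(d, irf, 1)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_true(all(c("tau1", "alpha1", "shift", "total", "background") %in% td$term))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_gt(gl$chi2_reduced, 0)
  expect_s3_class(autoplot(fit), "ggplot")
})
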