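test_that("steady-state anisotropy formula and bounds", {
  expect_equal(steady_state_anisotropy(100, 100), 0)
  expect_equal(steady_state_anisotropy(200, 100), 0.25)
  expect_equal(steady_state_anisotropy(1, 0), 1)
  expect_error(steady_state_anisotropy(0, 0), "Zero total")
  # bounds (-0.5, 1] with unit corrections, over random intensity pairs
  set.seed(1)
  p <- runif(500, 0, 100)
  q <- runif(500, 0.01, 100)
  r <- steady_state_anisotropy(p, q)
  expect_true(all(r > -0.5 & r <= 1))
})

test_that("G factor and NA-correction estimators", {
  expect_equal(estimate_g_factor(1000, 1000), 1)
  expect_equal(estimate_g_factor(1100, 1000), 1.1)
  g <- estimate_g_factor(1100, 1000)
  expect_equal(steady_state_anisotropy(1100, 1000, g = g), 0)
  expect_equal(estimate_na_correction(0.3, 0.3), 1)
  expect_equal(estimate_na_correction(0.35, 0.30), 0.35 / 0.30)
  expect_equal(estimate_na_correction(-0.35, -0.30), 0.35 / 0.30)
  expect_error(estimate_na_correction(0.3, 0), "non-zero")
})

test_that("anisotropy decay is zero for equal channels and masks empty channels", {
  time <- (0:499) * 0.05
  p <- decay_histogram(time, c(rep(0, 10), rep(100, 490)))
  ad <- anisotropy_decay(p, p, g = 1, min_total = 20)
  expect_true(all(ad$masked[1:10]))
  expect_true(all(ad$r[!ad$masked] == 0))
  expect_true(all(is.na(ad$r[ad$masked])))
})

test_that("anisotropy trace recovery is consistent with propagated errors", {
  irf <- make_irf(n_channels = 2048, window_ns = 50, center_ns = 2, seed = 31)
  pair <- make_polarized_pair(multiexp_model(1, 3.1), 0.35, 34, irf,
    counts_peak = 2e4, seed = 32
  )
  ad <- anisotropy_decay(pair$parallel, pair$perpendicular, min_total = 100)
  ok <- !ad$masked & ad$time > 2.2 # past the IRF
  # the channel clock includes the 2 ns IRF latency; the programmed r(t)
  # evolves in time after excitation
  r_true <- 0.35 * exp(-(ad$time[ok] - 2) / 34)
  cover <- mean(abs(ad$r[ok] - r_true) <= 2 * ad$sigma_r[ok])
  expect_gt(cover, 0.95) # ~95.4% expected for 2-sigma Gaussian coverage
})

test_that("rotational-correlation tail fit recovers theta and flags flat traces", {
  irf <- make_irf(n_channels = 3125, window_ns = 50, center_ns = 2, seed = 41)
  pair <- make_polarized_pair(multiexp_model(1, 3.1), 0.153, 34, irf,
    counts_peak = 1e5, seed = 42
  )
  ad <- anisotropy_decay(pair$parallel, pair$perpendicular)
  fit <- fit_rotational_correlation(ad, t_start = 5)
  expect_lt(abs(fit$theta_ns - 34) / 34, 0.10)
  expect_false(fit$no_decay)
  expect_named(glance(fit), c(
    "r_amplitude", "theta_ns", "no_decay",
    "n_channels", "converged"
  ))
  # flat r(t) = 0.2: theta at the bound, reported as no decay
  flat <- tibble::tibble(
    time = seq(0, 50, by = 0.05), r = 0.2,
    sigma_r = 0.001
  )
  expect_warning(fitf <- fit_rotational_correlation(flat, 5), "No anisotropy decay")
  expect_true(fitf$no_decay)
  expect_error(
    fit_rotational_correlation(flat[flat$time < 5.5, ], 5),
    "20 usable"
  )
})

test_that("Perrin conversions match the worked sensor values and invert exactly", {
  expect_equal(round(perrin_fundamental(0.14, 3.1, 34), 2), 0.15)
  expect_equal(round(perrin_fundamental(0.10, 3, 28), 2), 0.11)
  expect_equal(round(perrin_fundamental(-0.068, 3.0, 33), 3), -0.074)
  expect_equal(round(perrin_steady(1, 3.1, 34), 2), 0.92)
  expect_equal(round(perrin_steady(-0.033, 3.0, 33), 2), -0.03)
  expect_equal(perrin_fundamental(0.2, 3, Inf), 0.2)
  # exact round trip
  for (r0 in c(-0.074, 0.05, 0.153, 0.4)) {
    expect_equal(
      perrin_fundamental(perrin_steady(r0, 3.1, 34), 3.1, 34), r0,
      tolerance = 1e-12
    )
  }
  expect_error(perrin_steady(0.1, 3, -1), "theta")
})

test_that("Perrin steady-state anisotropy is monotone in theta", {
  thetas <- seq(1, 100, by = 1)
  expect_true(all(diff(perrin_steady(0.3, 3, thetas)) > 0))
  expect_true(all(diff(perrin_steady(-0.07, 3, thetas)) < 0))
})

test_that("bleed-through compensation reproduces the worked sensor anisotropies", {
  expect_equal(round(compensate_bleed_through(0.10, 0.35, 0.20), 3), 0.038)
  expect_equal(round(compensate_bleed_through(-0.03, 0.35, 0.09), 3), -0.068)
  expect_equal(compensate_bleed_through(0.123, 0.35, 0), 0.123)
  expect_error(compensate_bleed_through(0.1, 0.35, 1), "f_d")
})

test_that("compensation exactly inverts the two-species mixing model", {
  grid_r <- seq(-0.2, 0.4, by = 0.06)
  for (r_d in grid_r) {
    for (r_a in grid_r) {
      for (f_d in c(0, 0.2, 0.5, 0.95)) {
        r_obs <- r_d * f_d + r_a * (1 - f_d) # forward mixture
        expect_equal(compensate_bleed_through(r_obs, r_d, f_d), r_a,
          tolerance = 1e-12
        )
      }
    }
  }
})

test_that("dipole-angle conversion hits the canonical values and inverts", {
  expect_equal(angle_from_fundamental(0.4), 0)
  expect_equal(angle_from_fundamental(-0.2), 90)
  expect_equal(round(angle_from_fundamental(0), 1), 54.7)
  expect_equal(round(angle_from_fundamental(-0.074), 1), 62.7)
  expect_equal(round(angle_from_fundamental(0.153), 0), 40)
  expect_equal(fundamental_from_angle(0), 0.4)
  expect_lt(abs(fundamental_from_angle(54.7356)), 1e-6)
  expect_equal(round(fundamental_from_angle(62.7), 3), -0.074)
  expect_error(angle_from_fundamental(0.5), "real dipole angle")
  expect_error(fundamental_from_angle(91), "degrees")
  # identity on [0, 90] to 1e-9 degrees
  betas <- seq(0, 90, by = 0.5)
  expect_equal(angle_from_fundamental(fundamental_from_angle(betas)), betas,
    tolerance = 1e-9
  )
})
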