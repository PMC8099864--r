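uniform_stack <- function(r = 0.10, total = 1000, dims = c(16, 16, 20),
                          g = 1, poisson = TRUE, seed = 1) {
  p_exp <- array(total * (1 + 2 * r) / 3, dims)
  q_exp <- array(total * (1 - r) / 3 / g, dims)
  if (poisson) {
    set.seed(seed)
    p_exp[] <- rpois(length(p_exp), p_exp)
    q_exp[] <- rpois(length(q_exp), q_exp)
  }
  polarized_stack(p_exp, q_exp, g = g)
}

test_that("anisotropy maps recover a uniform anisotropy within shot noise", {
  st <- uniform_stack(r = 0.10, total = 1000)
  mov <- anisotropy_maps(st)
  expect_true(all(mov$mask))
  # first-order error propagation for r at this count level
  sigma_pred <- sqrt(2 / 3 * (1 - 0.10) * (1 + 2 * 0.10) *
    (1 - 0.10 + (1 + 2 * 0.10) / 2) / 1000) # ~ sqrt(2/(3N)) scale
  expect_lt(abs(mean(mov$r) - 0.10), 3 * sigma_pred / sqrt(length(mov$r)) + 1e-3)
  # empirical spread within 20% of the propagated prediction at >= 500 counts
  ad <- anisotropy_decay(
    decay_histogram(c(0, 1), c(1000 * 1.2 / 3, 1000 * 1.2 / 3)),
    decay_histogram(c(0, 1), c(1000 * 0.9 / 3, 1000 * 0.9 / 3)),
    min_total = 1
  )
  expect_lt(abs(sd(mov$r) - ad$sigma_r[1]) / ad$sigma_r[1], 0.2)
})

test_that("equal channels give a zero map and empty frames are masked", {
  p <- array(100, c(8, 8, 3))
  st <- polarized_stack(p, p)
  mov <- anisotropy_maps(st)
  expect_true(all(mov$r == 0))
  p2 <- p
  p2[, , 2] <- 0
  st2 <- polarized_stack(p2, p2)
  mov2 <- anisotropy_maps(st2)
  expect_true(all(!mov2$mask[, , 2]))
  expect_true(all(is.na(mov2$r[, , 2])))
})

test_that("display smoothing preserves constants and doubles the frame size", {
  st <- uniform_stack(r = 0.08, poisson = FALSE, dims = c(10, 12, 6))
  mov <- anisotropy_maps(st)
  sm <- smooth_for_display(mov)
  expect_equal(dim(sm$r)[1:2], c(20, 24))
  expect_equal(dim(sm$r)[3], 6)
  expect_true(all(abs(sm$r - 0.08) < 1e-9))
})

test_that("smoothing an impulse yields the configured Gaussian widths", {
  dims <- c(31, 31, 31)
  r <- array(0, dims)
  r[16, 16, 16] <- 1
  mov <- structure(
    list(
      r = r, mask = array(TRUE, dims),
      mean_intensity = matrix(1, dims[1], dims[2]), frame_interval = 1
    ),
    class = "anisotropy_movie"
  )
  sm <- smooth_for_display(mov, resize = FALSE)
  w <- sm$r / sum(sm$r)
  moment_sd <- function(margin) {
    m <- apply(w, margin, sum)
    idx <- seq_along(m)
    mu <- sum(idx * m)
    sqrt(sum((idx - mu)^2 * m))
  }
  expect_equal(moment_sd(1), 0.75, tolerance = 0.05)
  expect_equal(moment_sd(2), 0.75, tolerance = 0.05)
  expect_equal(moment_sd(3), 2.0, tolerance = 0.05)
})

test_that("IMD rendering clips, is monotone in r, and darkens dim pixels", {
  dims <- c(4, 4, 1)
  rvals <- matrix(seq(-0.05, 0.25, length.out = 16), 4, 4)
  mov <- structure(
    list(
      r = array(rvals, dims), mask = array(TRUE, dims),
      mean_intensity = matrix(1, 4, 4), frame_interval = 1
    ),
    class = "anisotropy_movie"
  )
  imd <- imd_render(mov, hue_range = c(0, 0.12))
  expect_equal(dim(imd), c(4, 4, 3, 1))
  expect_true(all(imd >= 0 & imd <= 255))
  # recover hue from rgb and check monotone non-decreasing in r within range
  hue_of <- function(i, j) {
    rgb <- imd[i, j, , 1]
    grDevices::rgb2hsv(rgb[1], rgb[2], rgb[3])[1]
  }
  hues <- mapply(hue_of, row(rvals), col(rvals))
  ord <- order(as.numeric(rvals))
  expect_true(all(diff(hues[ord]) >= -1e-9))
  # clipping: r below range renders at the lower hue bound
  expect_equal(hues[ord][1], hues[ord][2])
  # mid-range r maps to the hue midpoint
  mov$r[] <- 0.06
  imd_mid <- imd_render(mov, hue_range = c(0, 0.12), hue_span = c(0, 2 / 3))
  rgbm <- imd_mid[1, 1, , 1]
  expect_equal(as.numeric(grDevices::rgb2hsv(rgbm[1], rgbm[2], rgbm[3])[1]),
    1 / 3,
    tolerance = 0.01
  )
  # zero-intensity pixel renders black whatever its r
  mov$mean_intensity[1, 1] <- 0
  imd0 <- imd_render(mov)
  expect_true(all(imd0[1, 1, , 1] == 0))
  expect_error(imd_render(mov, hue_range = c(0.1, 0.1)), "increasing")
})

test_that("ROI traces equal the anisotropy of summed intensities", {
  st <- uniform_stack(r = 0.10, total = 800, dims = c(12, 12, 15), seed = 4)
  roi <- seq_len(12 * 12) - 1L # full frame, 0-based row-major
  tr <- roi_trace(st, roi)
  expect_equal(nrow(tr), 15)
  manual <- vapply(seq_len(15), function(f) {
    steady_state_anisotropy(
      sum(st$parallel[, , f]),
      sum(st$perpendicular[, , f])
    )
  }, numeric(1))
  expect_equal(tr$r, manual, tolerance = 1e-12)
  # single-pixel ROI equals that pixel's series
  tr1 <- roi_trace(st, 0L)
  pix <- vapply(
    seq_len(15),
    function(f) {
      steady_state_anisotropy(
        st$parallel[1, 1, f],
        st$perpendicular[1, 1, f]
      )
    },
    numeric(1)
  )
  expect_equal(tr1$r, pix)
  expect_error(roi_trace(st, integer(0)), "Empty")
})

test_that("ROI trace supports compensation and calibration to Ca2+", {
  st <- uniform_stack(r = 0.05, total = 5000, dims = c(8, 8, 12), poisson = FALSE)
  cal <- default_cal()
  tr <- roi_trace(st, seq_len(64) - 1L, cal = cal, f_d = 0.2, r_d = 0.35)
  expect_equal(tr$r_compensated,
    rep(compensate_bleed_through(0.05, 0.35, 0.2), 12),
    tolerance = 1e-9
  )
  expect_equal(tr$conc_nM,
    rep(as.numeric(invert_calibration(
      compensate_bleed_through(0.05, 0.35, 0.2), cal
    )), 12),
    tolerance = 1e-9
  )
})

test_that("channel SNR follows Poisson scaling", {
  mk <- function(mean_counts, seed) {
    set.seed(seed)
    arr <- array(rpois(400, mean_counts), c(1, 1, 400))
    polarized_stack(arr, arr)
  }
  st <- mk(400, 7)
  snr <- channel_snr(st, 0L)
  expect_equal(snr$snr[1], 20, tolerance = 0.15 * 20)
  st2 <- mk(800, 8)
  snr2 <- channel_snr(st2, 0L)
  expect_equal(snr2$snr[1] / snr$snr[1], sqrt(2), tolerance = 0.2)
  # constant signal flags infinite SNR
  stc <- polarized_stack(array(5, c(1, 1, 12)), array(5, c(1, 1, 12)))
  expect_warning(snrc <- channel_snr(stc, 0L), "infinite")
  expect_true(all(snrc$snr == Inf))
  expect_error(channel_snr(polarized_stack(
    array(1, c(2, 2, 3)),
    array(1, c(2, 2, 3))
  ), 0L), "10 frames")
})

test_that("polarized stacks round-trip through 16-bit TIFF", {
  st <- uniform_stack(dims = c(6, 6, 4), seed = 11)
  pp <- tempfile(fileext = ".tif")
  qq <- tempfile(fileext = ".tif")
  write_polarized_tiff(st, pp, qq)
  back <- read_polarized_tiff(pp, qq)
  expect_equal(back$parallel, st$parallel, tolerance = 1e-7)
  expect_equal(back$perpendicular, st$perpendicular, tolerance = 1e-7)
  unlink(c(pp, qq))
})
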