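# Two-channel polarized time-lapse stacks: anisotropy maps, display
# smoothing, IMD rendering, ROI traces, channel SNR.

#' Construct a polarized image stack
#'
#' Two co-registered single-channel time-lapse stacks (parallel and
#' perpendicular polarization) plus their correction factors. Arrays are
#' indexed `[row, column, frame]`; pixel coordinates elsewhere in the package
#' are 0-based row-major indices into a frame.
#'
#' @param parallel,perpendicular Non-negative numeric arrays of identical
#'   dimension `c(height, width, frames)`.
#' @param frame_interval Frame interval in seconds.
#' @param g G factor of the detection path.
#' @param f_corr High-NA depolarization correction factor.
#' @return An object of class `polarized_stack`.
#' @export
polarized_stack <- function(parallel, perpendicular, frame_interval = 1,
                            g = 1, f_corr = 1) {
  if (length(dim(parallel)) != 3 || !identical(dim(parallel), dim(perpendicular))) {
    abort("`parallel` and `perpendicular` must be 3-D arrays of identical shape.")
  }
  if (any(parallel < 0) || any(perpendicular < 0)) {
    abort("Intensities must be non-negative.")
  }
  stopifnot(frame_interval > 0, g > 0, f_corr > 0)
  structure(
    list(
      parallel = parallel, perpendicular = perpendicular,
      frame_interval = frame_interval, g = g, f_corr = f_corr
    ),
    class = "polarized_stack"
  )
}

#' @export
print.polarized_stack <- function(x, ...) {
  d <- dim(x$parallel)
  cat(sprintf(
    "Polarized image stack: %d x %d pixels, %d frames (dt = %.3g s), G = %.3g, f_corr = %.3g\n",
    d[1], d[2], d[3], x$frame_interval, x$g, x$f_corr
  ))
  invisible(x)
}

#' Per-pixel anisotropy maps from a polarized stack
#'
#' Applies the corrected anisotropy formula per pixel and frame. Pixels whose
#' total corrected intensity `I_par + 2 G I_perp` falls below `min_total` are
#' masked: at low counts the anisotropy variance explodes.
#'
#' @param stack A [polarized_stack()].
#' @param min_total Mask threshold in counts.
#' @return An object of class `anisotropy_movie`: `r` (array with NA at
#'   masked pixels), `mask` (logical array), `mean_intensity` (matrix,
#'   time-averaged total), `frame_interval`.
#' @export
anisotropy_maps <- function(stack, min_total = 50) {
  p <- stack$parallel
  q <- stack$perpendicular
  total <- p + 2 * stack$g * q
  mask <- total >= max(min_total, .Machine$double.eps)
  r <- array(NA_real_, dim(p))
  r[mask] <- stack$f_corr * (p[mask] - stack$g * q[mask]) / total[mask]
  structure(
    list(
      r = r, mask = mask,
      mean_intensity = apply(total, c(1, 2), mean),
      frame_interval = stack$frame_interval
    ),
    class = "anisotropy_movie"
  )
}

#' @export
print.anisotropy_movie <- function(x, ...) {
  d <- dim(x$r)
  cat(sprintf(
    "Anisotropy movie: %d x %d pixels, %d frames; %.1f%% of pixels valid\n",
    d[1], d[2], d[3], 100 * mean(x$mask)
  ))
  invisible(x)
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  radius <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution with reflective boundaries along margin `dim` of a 3-D array
convolve_margin <- function(x, kernel, margin) {
  if (length(kernel) == 1) return(x)
  radius <- (length(kernel) - 1) / 2
  n <- dim(x)[margin]
  idx <- c(rev(seq_len(min(radius, n))), seq_len(n), rev(n + 1 - seq_len(min(radius, n))))
  while (length(idx) < n + 2 * radius) idx <- c(idx[1], idx, idx[length(idx)])
  pad <- switch(margin,
    `1` = x[idx, , , drop = FALSE],
    `2` = x[, idx, , drop = FALSE],
    `3` = x[, , idx, drop = FALSE]
  )
  out <- array(0, dim(x))
  for (j in seq_along(kernel)) {
    sl <- switch(margin,
      `1` = pad[(j - 1) + seq_len(n), , , drop = FALSE],
      `2` = pad[, (j - 1) + seq_len(n), , drop = FALSE],
      `3` = pad[, , (j - 1) + seq_len(n), drop = FALSE]
    )
    out <- out + kernel[j] * sl
  }
  out
}

# bilinear 2x spatial upsampling of each frame of a 3-D array
upsample2_frames <- function(x) {
  d <- dim(x)
  # sample at half-pixel positions, clamped at the borders
  coord <- function(n) pmin(pmax((seq_len(2 * n) - 0.5) / 2 + 0.5, 1), n)
  ry <- coord(d[1])
  rx <- coord(d[2])
  y0 <- floor(ry); y1 <- pmin(y0 + 1, d[1]); fy <- ry - y0
  x0 <- floor(rx); x1 <- pmin(x0 + 1, d[2]); fx <- rx - x0
  colscale <- function(m, w) t(t(m) * w)
  out <- array(0, c(2 * d[1], 2 * d[2], d[3]))
  for (f in seq_len(d[3])) {
    fr <- x[, , f]
    out[, , f] <- (1 - fy) * (colscale(fr[y0, x0, drop = FALSE], 1 - fx) +
      colscale(fr[y0, x1, drop = FALSE], fx)) +
      fy * (colscale(fr[y1, x0, drop = FALSE], 1 - fx) +
        colscale(fr[y1, x1, drop = FALSE], fx))
  }
  out
}

#' Smooth an anisotropy movie for display
#'
#' Upsamples each frame 2x (bilinear) and applies a separable Gaussian filter
#' with spatial standard deviation `sigma_xy` (in post-resize pixels) and
#' temporal standard deviation `sigma_t` (in frames), with reflective
#' boundaries. Masked pixels are handled by normalized convolution (values
#' and mask filtered jointly); the mask itself is propagated.
#'
#' @param movie An `anisotropy_movie` from [anisotropy_maps()].
#' @param sigma_xy Spatial Gaussian sigma in pixels (after resizing).
#' @param sigma_t Temporal Gaussian sigma in frames.
#' @param resize If `TRUE` (default), frames are upsampled 2x first.
#' @return A smoothed `anisotropy_movie`.
#' @export
smooth_for_display <- function(movie, sigma_xy = 0.75, sigma_t = 2,
                               resize = TRUE) {
  r <- movie$r
  m <- movie$mask * 1
  if (resize) {
    r[!movie$mask] <- 0
    r <- upsample2_frames(r)
    m <- upsample2_frames(m)
  } else {
    r[is.na(r)] <- 0
  }
  ks <- gaussian_kernel_1d(sigma_xy)
  kt <- gaussian_kernel_1d(sigma_t)
  num <- convolve_margin(convolve_margin(convolve_margin(r * (m > 0.5), ks, 1), ks, 2), kt, 3)
  den <- convolve_margin(convolve_margin(convolve_margin((m > 0.5) * 1, ks, 1), ks, 2), kt, 3)
  mask <- m > 0.5
  out <- array(NA_real_, dim(num))
  ok <- mask & den > 0
  out[ok] <- num[ok] / den[ok]
  mi <- movie$mean_intensity
  if (resize) {
    mi <- upsample2_frames(array(mi, c(dim(mi), 1)))[, , 1]
  }
  structure(
    list(
      r = out, mask = mask, mean_intensity = mi,
      frame_interval = movie$frame_interval
    ),
    class = "anisotropy_movie"
  )
}

#' Render an anisotropy movie as an intensity-modulated display (IMD)
#'
#' Anisotropy values are clipped to `hue_range` and mapped linearly onto a
#' hue interval (monotone non-decreasing in r); saturation is maximal; value
#' (brightness) is the time-averaged total intensity normalized to \[0, 1\],
#' so dim pixels render dark regardless of their anisotropy. Output frames
#' are 8-bit RGB.
#'
#' @param movie An `anisotropy_movie`.
#' @param hue_range Anisotropy interval mapped onto the hue axis
#'   (values outside are set to the nearest bound).
#' @param hue_span Hue endpoints in \[0, 1\] (HSV hue) for the low and high
#'   ends of `hue_range`.
#' @return An array of class `imd_movie`, dimension
#'   `c(height, width, 3, frames)`, integer 0-255.
#' @export
imd_render <- function(movie, hue_range = c(0, 0.12), hue_span = c(0, 2 / 3)) {
  if (diff(hue_range) <= 0) abort("`hue_range` must be an increasing interval.")
  d <- dim(movie$r)
  v <- movie$mean_intensity / max(movie$mean_intensity, 1e-12)
  out <- array(0L, c(d[1], d[2], 3, d[3]))
  for (f in seq_len(d[3])) {
    r <- movie$r[, , f]
    r[is.na(r)] <- hue_range[1]
    h_frac <- (pmin(pmax(r, hue_range[1]), hue_range[2]) - hue_range[1]) /
      diff(hue_range)
    hue <- hue_span[1] + h_frac * (hue_span[2] - hue_span[1])
    rgb <- grDevices::col2rgb(grDevices::hsv(hue, s = 1, v = pmin(pmax(v, 0), 1)))
    out[, , 1, f] <- matrix(rgb[1, ], d[1], d[2])
    out[, , 2, f] <- matrix(rgb[2, ], d[1], d[2])
    out[, , 3, f] <- matrix(rgb[3, ], d[1], d[2])
  }
  structure(out, class = "imd_movie", hue_range = hue_range, hue_span = hue_span)
}

# resolve a 0-based row-major pixel index set (or logical mask) to array
# (row, col) indices of a height x width frame
resolve_roi <- function(roi, height, width) {
  if (is.matrix(roi) && is.logical(roi)) {
    if (!all(dim(roi) == c(height, width))) abort("ROI mask shape mismatch.")
    return(which(roi, arr.ind = TRUE))
  }
  roi <- as.integer(roi)
  if (length(roi) == 0) abort("Empty ROI.")
  if (any(roi < 0) || any(roi >= height * width)) {
    abort("ROI indices out of range (0-based row-major expected).")
  }
  cbind(row = roi %/% width + 1L, col = roi %% width + 1L)
}

#' ROI anisotropy (and Ca2+) time trace from a polarized stack
#'
#' Per-frame anisotropy is computed from the ROI-summed channel intensities
#' (ratio of sums, not mean of per-pixel ratios, the lower-variance
#' estimator). Optional donor bleed-through compensation at the ROI level
#' (see [compensate_bleed_through()]) and Hill-calibration inversion to free
#' Ca2+ are applied to the summed trace.
#'
#' @param stack A [polarized_stack()].
#' @param roi Pixel set: 0-based row-major integer indices, or a logical
#'   `height x width` mask.
#' @param cal Optional [hill_calibration()] (or `hill_fit`); adds a
#'   `conc_nM` column.
#' @param f_d Optional donor fraction for bleed-through compensation; adds an
#'   `r_compensated` column (used for the calibration inversion when given).
#' @param r_d Donor anisotropy used in the compensation.
#' @return A tibble with columns `frame` (0-based), `time_s`, `r`, and
#'   optionally `r_compensated`, `conc_nM`.
#' @export
roi_trace <- function(stack, roi, cal = NULL, f_d = NULL, r_d = 0.35) {
  d <- dim(stack$parallel)
  px <- resolve_roi(roi, d[1], d[2])
  n_frames <- d[3]
  sum_roi <- function(arr) {
    vapply(seq_len(n_frames), function(f) {
      sum(arr[, , f][px])
    }, numeric(1))
  }
  p <- sum_roi(stack$parallel)
  q <- sum_roi(stack$perpendicular)
  r <- steady_state_anisotropy(p, q, g = stack$g, f_corr = stack$f_corr)
  out <- tibble(
    frame = seq_len(n_frames) - 1L,
    time_s = (seq_len(n_frames) - 1L) * stack$frame_interval,
    r = r
  )
  r_for_cal <- r
  if (!is.null(f_d)) {
    out$r_compensated <- compensate_bleed_through(r, r_d = r_d, f_d = f_d)
    r_for_cal <- out$r_compensated
  }
  if (!is.null(cal)) {
    if (inherits(cal, "hill_fit")) cal <- cal$calibration
    out$conc_nM <- suppressWarnings(as.numeric(invert_calibration(r_for_cal, cal)))
  }
  out
}

#' Signal-to-noise ratio of the two polarization channels over an ROI
#'
#' Per channel, the ROI-summed signal is reduced to mean over temporal
#' standard deviation across frames. A constant (noiseless) signal yields
#' `Inf` with a warning.
#'
#' @param stack A [polarized_stack()] with at least 10 frames.
#' @param roi Pixel set as in [roi_trace()].
#' @return A tibble with columns `channel` and `snr`.
#' @export
channel_snr <- function(stack, roi) {
  d <- dim(stack$parallel)
  if (d[3] < 10) abort("Need at least 10 frames for an SNR estimate.")
  px <- resolve_roi(roi, d[1], d[2])
  sum_roi <- function(arr) {
    vapply(seq_len(d[3]), function(f) sum(arr[, , f][px]), numeric(1))
  }
  snr1 <- function(x) {
    s <- sd(x)
    if (s == 0) {
      warn("Constant signal: SNR is infinite.")
      return(Inf)
    }
    mean(x) / s
  }
  tibble(
    channel = c("parallel", "perpendicular"),
    snr = c(snr1(sum_roi(stack$parallel)), snr1(sum_roi(stack$perpendicular)))
  )
}

#' Plot an ROI anisotropy trace
#'
#' @param trace Tibble from [roi_trace()].
#' @return A ggplot object (anisotropy vs time; compensated trace overlaid
#'   when present).
#' @export
plot_roi_trace <- function(trace) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_s, y = .data$r)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "anisotropy r")
  if (!is.null(trace$r_compensated)) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(y = .data$r_compensated),
      colour = "red"
    )
  }
  p
}
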