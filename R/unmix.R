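# Linear spectral unmixing of donor and acceptor emission contributions.

#' Construct an emission spectrum
#'
#' @param wavelength Wavelengths in nm, strictly increasing.
#' @param intensity Non-negative intensities (a.u.), same length.
#' @param label Optional label carried as an attribute.
#' @return A tibble with columns `wavelength` and `intensity`.
#' @export
emission_spectrum <- function(wavelength, intensity, label = NULL) {
  if (length(wavelength) != length(intensity)) {
    abort("`wavelength` and `intensity` must have the same length.")
  }
  if (any(diff(wavelength) <= 0)) abort("`wavelength` must be strictly increasing.")
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    abort("`intensity` must be finite and non-negative.")
  }
  out <- tibble(wavelength = as.numeric(wavelength), intensity = as.numeric(intensity))
  if (!is.null(label)) attr(out, "label") <- label
  out
}

resample_spectrum <- function(ref, grid) {
  approx(ref$wavelength, ref$intensity, xout = grid, rule = 1)$y
}

#' Unmix a measured spectrum into donor and acceptor contributions
#'
#' Non-negative least squares for the coefficients `(c_d, c_a)` minimizing
#' `||measured - c_d * D - c_a * A||^2`, after linear resampling of both
#' reference spectra onto the measured wavelength grid. Only the grid overlap
#' of all three spectra is used.
#'
#' @param measured Measured emission spectrum (tibble `wavelength`,
#'   `intensity`).
#' @param donor_ref,acceptor_ref Reference emission spectra of the pure
#'   donor and acceptor.
#' @param offset If `TRUE`, an unconstrained constant baseline is included.
#' @return An object of class `unmix_fit` with `coeff_donor`,
#'   `coeff_acceptor`, `offset`, `residual_norm`, and a `fractions` tibble
#'   (per-wavelength donor fraction of the fitted signal).
#' @examples
#' s <- make_spectra(band_fraction = 0.2, seed = 1)
#' fit <- unmix(s$mixture, s$donor_ref, s$acceptor_ref)
#' donor_fraction_cumulative(fit, 530, 620)
#' @export
unmix <- function(measured, donor_ref, acceptor_ref, offset = FALSE) {
  grid <- measured$wavelength
  d <- resample_spectrum(donor_ref, grid)
  a <- resample_spectrum(acceptor_ref, grid)
  keep <- is.finite(d) & is.finite(a)
  if (sum(keep) < 3) abort("Grid overlap of measured and reference spectra is too small.")
  grid <- grid[keep]
  d <- d[keep]
  a <- a[keep]
  y <- measured$intensity[keep]
  # identifiability: proportional references leave c_d, c_a undetermined
  nd <- d / sqrt(sum(d^2))
  na <- a / sqrt(sum(a^2))
  if (1 - abs(sum(nd * na)) < 1e-10) {
    abort("Reference spectra are proportional; unmixing is unidentifiable.")
  }
  if (offset) {
    # allow a signed baseline under NNLS by giving it +1 and -1 columns
    basis <- cbind(d, a, 1, -1)
  } else {
    basis <- cbind(d, a)
  }
  sol <- pracma::lsqnonneg(basis, y)
  cd <- sol$x[1]
  ca <- sol$x[2]
  off <- if (offset) sol$x[3] - sol$x[4] else 0
  fitted <- cd * d + ca * a + off
  denom <- cd * d + ca * a
  frac <- ifelse(denom > 0, cd * d / denom, NA_real_)
  structure(
    list(
      coeff_donor = cd, coeff_acceptor = ca, offset = off,
      residual_norm = sqrt(sum((y - fitted)^2)),
      fractions = tibble(
        wavelength = grid, measured = y, fitted = fitted,
        donor = cd * d, acceptor = ca * a, donor_fraction = frac
      )
    ),
    class = "unmix_fit"
  )
}

#' @export
print.unmix_fit <- function(x, ...) {
  cat(sprintf(
    "Linear unmixing: c_donor = %.4g, c_acceptor = %.4g (residual norm %.3g)\n",
    x$coeff_donor, x$coeff_acceptor, x$residual_norm
  ))
  invisible(x)
}

#' @rdname unmix
#' @param x,object An `unmix_fit` object.
#' @param ... Unused.
#' @export
tidy.unmix_fit <- function(x, ...) {
  tibble(
    term = c("coeff_donor", "coeff_acceptor", "offset"),
    estimate = c(x$coeff_donor, x$coeff_acceptor, x$offset)
  )
}

#' @rdname unmix
#' @export
glance.unmix_fit <- function(x, ...) {
  tibble(
    coeff_donor = x$coeff_donor, coeff_acceptor = x$coeff_acceptor,
    residual_norm = x$residual_norm,
    n_wavelengths = nrow(x$fractions)
  )
}

#' @rdname unmix
#' @export
autoplot.unmix_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$fractions,
    c("measured", "fitted", "donor", "acceptor"),
    names_to = "component", values_to = "intensity"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$wavelength, y = .data$intensity,
    colour = .data$component
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "intensity (a.u.)")
}

# trapezoid integral of a sampled curve over [lo, hi], interpolating the
# band edges onto the curve
band_trapz <- function(wavelength, y, lo, hi) {
  if (hi <= lo) abort("Empty integration band.")
  inside <- wavelength > lo & wavelength < hi
  xs <- wavelength[inside]
  ys <- y[inside]
  if (lo >= min(wavelength)) {
    xs <- c(lo, xs)
    ys <- c(approx(wavelength, y, lo)$y, ys)
  }
  if (hi <= max(wavelength)) {
    xs <- c(xs, hi)
    ys <- c(ys, approx(wavelength, y, hi)$y)
  }
  if (length(xs) < 2) abort("Integration band does not overlap the spectrum grid.")
  pracma::trapz(xs, ys)
}

#' Cumulative donor fraction over a wavelength band
#'
#' Fraction of the fitted signal attributable to the donor, integrated over
#' `[lambda_min, lambda_max]` by the trapezoidal rule. This is the donor
#' bleed-through fraction `f_d` that enters [compensate_bleed_through()] when
#' the band is the acceptor detection band.
#'
#' @param result An `unmix_fit` from [unmix()].
#' @param lambda_min,lambda_max Band limits in nm.
#' @return Donor fraction of the total fitted signal in the band.
#' @export
donor_fraction_cumulative <- function(result, lambda_min, lambda_max) {
  fr <- result$fractions
  num <- band_trapz(fr$wavelength, fr$donor, lambda_min, lambda_max)
  den <- band_trapz(fr$wavelength, fr$donor + fr$acceptor, lambda_min, lambda_max)
  if (den <= 0) {
    return(0)
  }
  num / den
}

#' Interpolated peak-intensity ratio of a spectrum
#'
#' Intensity at `lambda_a` divided by intensity at `lambda_b`, each linearly
#' interpolated on the spectrum grid. Used e.g. for absorption-band ratios in
#' donor-acceptor stoichiometry estimates.
#'
#' @param spectrum A spectrum tibble (`wavelength`, `intensity`).
#' @param lambda_a,lambda_b Wavelengths in nm within the grid range.
#' @return Dimensionless intensity ratio.
#' @export
peak_ratio <- function(spectrum, lambda_a, lambda_b) {
  rng <- range(spectrum$wavelength)
  if (lambda_a < rng[1] || lambda_a > rng[2] || lambda_b < rng[1] ||
    lambda_b > rng[2]) {
    abort("Both wavelengths must lie within the spectrum grid.")
  }
  ia <- approx(spectrum$wavelength, spectrum$intensity, lambda_a)$y
  ib <- approx(spectrum$wavelength, spectrum$intensity, lambda_b)$y
  if (ib == 0) abort("Zero intensity at the denominator wavelength.")
  ia / ib
}
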