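# Steady-state and time-resolved anisotropy, Perrin conversion, bleed-through
# compensation, and dipole-angle inversion.

#' Steady-state fluorescence anisotropy with instrument corrections
#'
#' `r = f_corr * (I_par - G * I_perp) / (I_par + 2 * G * I_perp)`, where `G`
#' compensates unequal detection efficiency of the two polarization channels
#' and `f_corr` compensates depolarization by high-NA objectives.
#'
#' @param i_parallel,i_perpendicular Non-negative intensities (vectorized).
#' @param g G factor (> 0).
#' @param f_corr High-NA depolarization correction factor (> 0).
#' @return Anisotropy (dimensionless); with `g = f_corr = 1` it lies in
#'   (-0.5, 1\].
#' @examples
#' steady_state_anisotropy(200, 100) # 0.25
#' @export
steady_state_anisotropy <- function(i_parallel, i_perpendicular, g = 1,
                                    f_corr = 1) {
  stopifnot(g > 0, f_corr > 0)
  if (any(i_parallel < 0) || any(i_perpendicular < 0)) {
    abort("Intensities must be non-negative.")
  }
  total <- i_parallel + 2 * g * i_perpendicular
  if (any(total <= 0)) abort("Zero total intensity: anisotropy undefined.")
  f_corr * (i_parallel - g * i_perpendicular) / total
}

#' G factor from a zero-anisotropy reference
#'
#' For a reference fluorophore whose true steady-state anisotropy is zero
#' (small, long-lifetime dye), the detection-efficiency ratio is simply
#' `G = I_par / I_perp`.
#'
#' @param reference_parallel,reference_perpendicular Reference intensities
#'   (> 0).
#' @return The G factor.
#' @export
estimate_g_factor <- function(reference_parallel, reference_perpendicular) {
  if (any(reference_parallel <= 0) || any(reference_perpendicular <= 0)) {
    abort("Reference intensities must be > 0.")
  }
  reference_parallel / reference_perpendicular
}

#' High-NA depolarization correction factor
#'
#' Ratio of the anisotropy measured with a low-NA objective (taken as
#' unbiased) over the observed high-NA anisotropy of the same sample.
#'
#' @param r_low_na Anisotropy with the low-NA objective.
#' @param r_high_na_obs Observed anisotropy with the high-NA objective
#'   (non-zero).
#' @return The correction factor `f_corr`.
#' @export
estimate_na_correction <- function(r_low_na, r_high_na_obs) {
  if (any(r_high_na_obs == 0)) abort("Observed anisotropy must be non-zero.")
  r_low_na / r_high_na_obs
}

#' Time-resolved anisotropy from a polarized decay pair
#'
#' Applies the corrected anisotropy formula per time channel to a pair of
#' polarized TCSPC histograms and propagates Poisson counting uncertainty to
#' each r(t) value. Channels whose total corrected intensity falls below
#' `min_total` are masked (r set to NA).
#'
#' @param parallel,perpendicular Decay tibbles on matching grids.
#' @param g,f_corr Correction factors as in [steady_state_anisotropy()].
#' @param min_total Minimum `I_par + 2 G I_perp` for a channel to be kept.
#' @return A tibble with columns `time`, `r`, `sigma_r`, `total`, `masked`.
#' @export
anisotropy_decay <- function(parallel, perpendicular, g = 1, f_corr = 1,
                             min_total = 20) {
  check_same_grid(parallel, perpendicular)
  stopifnot(g > 0, f_corr > 0)
  p <- parallel$counts
  q <- perpendicular$counts
  total <- p + 2 * g * q
  ok <- total >= max(min_total, 1)
  r <- rep(NA_real_, length(p))
  sigma <- rep(NA_real_, length(p))
  r[ok] <- f_corr * (p[ok] - g * q[ok]) / total[ok]
  # var(r) from Poisson channel variances: dr/dP = 3 G Q / T^2, dr/dQ = -3 G P / T^2
  sigma[ok] <- f_corr * 3 * g *
    sqrt(q[ok]^2 * p[ok] + p[ok]^2 * q[ok]) / total[ok]^2
  tibble(
    time = parallel$time, r = r, sigma_r = sigma, total = total,
    masked = !ok
  )
}

#' Fit a mono-exponential rotational-correlation decay to an anisotropy tail
#'
#' Weighted least-squares fit of `r(t) = A * exp(-t / theta)` to the
#' anisotropy trace for `t >= t_start`, using the propagated per-channel
#' uncertainties as weights. The tail window excludes the fast initial
#' depolarization (FRET-induced angular displacement), leaving Brownian
#' rotational diffusion.
#'
#' @param decay Anisotropy tibble from [anisotropy_decay()] (columns `time`,
#'   `r`, and optionally `sigma_r`).
#' @param t_start Start of the fitted tail in ns.
#' @param theta_max Upper bound for theta; a fit at the bound is reported as
#'   "no decay detected".
#' @return An object of class `rot_fit` with `r_amplitude`, `theta_ns`,
#'   `no_decay`, `std_errors`.
#' @export
fit_rotational_correlation <- function(decay, t_start = 5, theta_max = 1e4) {
  use <- decay$time >= t_start & is.finite(decay$r)
  if (sum(use) < 20) {
    abort("Need at least 20 usable channels after `t_start`.")
  }
  t <- decay$time[use]
  r <- decay$r[use]
  w <- if (!is.null(decay$sigma_r)) {
    s <- decay$sigma_r[use]
    s[!is.finite(s) | s <= 0] <- median(s[is.finite(s) & s > 0])
    1 / s
  } else {
    rep(1, length(r))
  }
  a0 <- mean(head(r, max(5, length(r) %/% 20)))
  if (!is.finite(a0) || a0 == 0) a0 <- mean(r)
  theta0 <- diff(range(t)) / max(log(abs(a0) / max(abs(mean(tail(r, 10)))), 1e-3), 0.1)
  theta0 <- min(max(abs(theta0), 1), theta_max / 10)
  resid_fn <- function(par) (r - par[1] * exp(-t / exp(par[2]))) * w
  fit <- minpack.lm::nls.lm(
    par = c(a0, log(theta0)),
    lower = c(-Inf, log(1e-3)), upper = c(Inf, log(theta_max)),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (fit$info == 0 || fit$info == 5) {
    warn("Rotational-correlation fit did not converge.")
  }
  theta <- exp(fit$par[2])
  no_decay <- theta >= 0.95 * theta_max
  if (no_decay) warn("No anisotropy decay detected within the window (theta at bound).")
  se <- tryCatch(
    {
      cv <- solve(fit$hessian)
      c(sqrt(cv[1, 1]), theta * sqrt(cv[2, 2]))
    },
    error = function(e) c(NA_real_, NA_real_)
  )
  structure(
    list(
      r_amplitude = fit$par[1], theta_ns = theta, no_decay = no_decay,
      std_errors = setNames(se, c("r_amplitude", "theta_ns")),
      t_start = t_start, n_channels = sum(use),
      converged = !(fit$info %in% c(0, 5))
    ),
    class = "rot_fit"
  )
}

#' @export
print.rot_fit <- function(x, ...) {
  cat(sprintf(
    "Rotational-correlation tail fit (t >= %.3g ns, %d channels)\n",
    x$t_start, x$n_channels
  ))
  if (x$no_decay) {
    cat("  no decay detected (theta at upper bound)\n")
  } else {
    cat(sprintf(
      "  A = %.4g, theta = %.4g ns\n", x$r_amplitude, x$theta_ns
    ))
  }
  invisible(x)
}

#' @rdname fit_rotational_correlation
#' @param x,object A `rot_fit` object.
#' @param ... Unused.
#' @export
tidy.rot_fit <- function(x, ...) {
  tibble(
    term = c("r_amplitude", "theta_ns"),
    estimate = c(x$r_amplitude, x$theta_ns),
    std.error = unname(x$std_errors)
  )
}

#' @rdname fit_rotational_correlation
#' @export
glance.rot_fit <- function(x, ...) {
  tibble(
    r_amplitude = x$r_amplitude, theta_ns = x$theta_ns,
    no_decay = x$no_decay, n_channels = x$n_channels,
    converged = x$converged
  )
}

#' Perrin equation: fundamental anisotropy from steady-state anisotropy
#'
#' `r0 = r * (1 + tau / theta)`: undoes the depolarization by rotational
#' diffusion during the excited-state lifetime.
#'
#' @param r Steady-state anisotropy.
#' @param tau Fluorescence lifetime in ns (>= 0).
#' @param theta Rotational correlation time in ns (> 0; `Inf` allowed).
#' @return Fundamental anisotropy r0.
#' @examples
#' perrin_fundamental(0.14, 3.1, 34) # 0.153
#' @export
perrin_fundamental <- function(r, tau, theta) {
  if (any(theta <= 0)) abort("`theta` must be > 0.")
  if (any(tau < 0)) abort("`tau` must be >= 0.")
  r * (1 + tau / theta)
}

#' Perrin equation: steady-state anisotropy from fundamental anisotropy
#'
#' `r = r0 / (1 + tau / theta)`; exact inverse of [perrin_fundamental()].
#'
#' @param r0 Fundamental anisotropy.
#' @inheritParams perrin_fundamental
#' @return Steady-state anisotropy.
#' @examples
#' perrin_steady(1, 3.1, 34) # 0.916: diffusion keeps 92% of r0
#' @export
perrin_steady <- function(r0, tau, theta) {
  if (any(theta <= 0)) abort("`theta` must be > 0.")
  if (any(tau < 0)) abort("`tau` must be >= 0.")
  r0 / (1 + tau / theta)
}

#' Donor bleed-through compensation of sensitized-acceptor anisotropy
#'
#' In a two-species mixture the observed anisotropy is the intensity-weighted
#' mean `r_obs = r_d * f_d + r_a * (1 - f_d)`; solving for the acceptor term
#' gives `r_a = (r_obs - r_d * f_d) / (1 - f_d)`. `f_d` is the donor fraction
#' of the total signal in the acceptor detection band, typically taken from
#' spectral unmixing (see [donor_fraction_cumulative()]).
#'
#' @param r_obs Observed anisotropy of the mixed signal.
#' @param r_d Donor anisotropy; defaults to 0.35, the steady-state anisotropy
#'   of the free dim donor.
#' @param f_d Donor fraction of the total signal, in \[0, 1).
#' @return The compensated sensitized-acceptor anisotropy.
#' @examples
#' compensate_bleed_through(0.10, 0.35, 0.20) # 0.0375
#' compensate_bleed_through(-0.03, 0.35, 0.09) # -0.0676
#' @export
compensate_bleed_through <- function(r_obs, r_d = 0.35, f_d) {
  if (any(f_d < 0) || any(f_d >= 1)) abort("`f_d` must be in [0, 1).")
  (r_obs - r_d * f_d) / (1 - f_d)
}

#' Dipole angle from fundamental anisotropy
#'
#' Inverts `r0 = 0.4 * (3 cos^2(beta) - 1) / 2` for the angle `beta` between
#' the absorption and emission transition dipole moments (for sensitized
#' acceptors: between donor absorption and acceptor emission dipoles). The
#' 0.4 prefactor is the collinear-dipole limit.
#'
#' @param r0 Fundamental anisotropy in \[-0.2, 0.4\].
#' @return Angle in degrees, in \[0, 90\].
#' @examples
#' angle_from_fundamental(0) # 54.7 (magic angle)
#' angle_from_fundamental(-0.074) # 62.7
#' @export
angle_from_fundamental <- function(r0) {
  if (any(r0 < -0.2 - 1e-12) || any(r0 > 0.4 + 1e-12)) {
    abort("`r0` must lie in [-0.2, 0.4] for a real dipole angle.")
  }
  r0 <- pmin(pmax(r0, -0.2), 0.4)
  acos(sqrt((5 * r0 + 1) / 3)) * 180 / pi
}

#' Fundamental anisotropy from dipole angle
#'
#' Forward direction of [angle_from_fundamental()]:
#' `r0 = 0.4 * (3 cos^2(beta) - 1) / 2`.
#'
#' @param beta Angle in degrees, in \[0, 90\].
#' @return Fundamental anisotropy.
#' @export
fundamental_from_angle <- function(beta) {
  if (any(beta < 0) || any(beta > 90)) abort("`beta` must be in [0, 90] degrees.")
  b <- beta * pi / 180
  0.4 * (3 * cos(b)^2 - 1) / 2
}

#' Plot a time-resolved anisotropy trace
#'
#' @param decay Tibble from [anisotropy_decay()].
#' @param fit Optional `rot_fit` whose tail model is overlaid.
#' @return A ggplot object.
#' @export
plot_anisotropy_decay <- function(decay, fit = NULL) {
  p <- ggplot2::ggplot(
    dplyr::filter(decay, !.data$masked),
    ggplot2::aes(x = .data$time, y = .data$r)
  ) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::labs(x = "time (ns)", y = "anisotropy r(t)")
  if (!is.null(fit)) {
    tt <- seq(fit$t_start, max(decay$time), length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble(time = tt, r = fit$r_amplitude * exp(-tt / fit$theta_ns)),
      colour = "red"
    )
  }
  p
}
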