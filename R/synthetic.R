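# Seed-deterministic generators for every input kind the toolkit analyses:
# TCSPC decays and IRFs, polarized decay pairs, emission spectra, anisotropy
# titrations, and polarized cell movies.

with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (requireNamespace("withr", quietly = TRUE)) {
    withr::with_seed(seed, code)
  } else {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit(
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    )
    set.seed(seed)
    force(code)
  }
}

#' Simulate a measured instrument response function
#'
#' Gaussian temporal profile with the stated full width at half maximum
#' (42 ps is typical of a fast microchannel-plate TCSPC chain), centered at
#' `center_ns`, scaled to `total_counts` and Poisson-sampled. A zero FWHM
#' yields a single-channel delta.
#'
#' @param n_channels Number of channels (cuvette default 4096).
#' @param window_ns Time window in ns (20 or 40 ns in cuvette mode; 50 ns
#'   with 3125 channels in microscope mode).
#' @param fwhm_ns IRF full width at half maximum in ns.
#' @param center_ns Position of the IRF peak in ns.
#' @param total_counts Total counts in the IRF histogram.
#' @param poisson If `FALSE`, return the noiseless expected histogram.
#' @param seed Random seed (fixed seed gives identical output).
#' @return A decay tibble (see [decay_histogram()]) with attribute
#'   `fwhm_estimate`.
#' @export
make_irf <- function(n_channels = 4096, window_ns = 20, fwhm_ns = 0.042,
                     center_ns = window_ns / 20, total_counts = 1e6,
                     poisson = TRUE, seed = NULL) {
  dwell <- window_ns / n_channels
  time <- (seq_len(n_channels) - 1) * dwell
  if (fwhm_ns > 0 && fwhm_ns < dwell) {
    warn("IRF FWHM below the channel width; profile is under-sampled.")
  }
  if (fwhm_ns <= 0) {
    shape <- numeric(n_channels)
    shape[which.min(abs(time - center_ns))] <- 1
  } else {
    sigma <- fwhm_ns / (2 * sqrt(2 * log(2)))
    shape <- exp(-(time - center_ns)^2 / (2 * sigma^2))
  }
  expected <- shape / sum(shape) * total_counts
  counts <- if (poisson) with_seed(seed, rpois(n_channels, expected)) else expected
  out <- decay_histogram(time, counts)
  attr(out, "fwhm_estimate") <- fwhm_ns
  out
}

#' Simulate a TCSPC decay histogram
#'
#' Convolves the model with the IRF, scales the curve so its maximum equals
#' `counts_peak` (decays are conventionally recorded to a fixed peak count,
#' 10,000 by default), adds the background, and Poisson-samples each channel.
#'
#' @param model A [multiexp_model()].
#' @param irf IRF histogram defining the grid (from [make_irf()] or
#'   measured).
#' @param counts_peak Expected counts in the peak channel.
#' @param background Expected background counts per channel.
#' @param poisson If `FALSE`, return the noiseless expected curve.
#' @param seed Random seed.
#' @return A decay tibble on the IRF grid.
#' @examples
#' irf <- make_irf(n_channels = 1024, seed = 1)
#' d <- make_decay(multiexp_model(c(0.7, 0.3), c(0.58, 1.7)), irf, seed = 2)
#' @export
make_decay <- function(model, irf, counts_peak = 1e4, background = 0,
                       poisson = TRUE, seed = NULL) {
  shape <- convolve_model(model, irf)
  expected <- shape / max(shape) * counts_peak + background
  counts <- if (poisson) {
    with_seed(seed, rpois(length(expected), expected))
  } else {
    expected
  }
  decay_histogram(irf$time, counts)
}

#' Simulate a polarized TCSPC decay pair
#'
#' The total-intensity model curve is split into polarized components using
#' `I_par = I (1 + 2 r) / 3` and `I_perp = I (1 - r) / 3` with
#' `r(t) = r0_fast * exp(-t / theta)` (single rotational correlation time;
#' `r0_fast` is the anisotropy remaining after any sub-resolution fast
#' depolarization, e.g. FRET-induced angular displacement). Each component is
#' convolved with the IRF; the perpendicular channel is divided by the
#' detection-efficiency ratio `g` so that the corrected anisotropy formula
#' with this `g` recovers `r(t)` in expectation. Channels are
#' Poisson-sampled.
#'
#' @param total_model [multiexp_model()] of the total fluorescence decay.
#' @param r0_fast Initial anisotropy of the slow depolarization phase
#'   (|r0_fast| <= 0.4).
#' @param theta_ns Rotational correlation time in ns.
#' @param irf IRF histogram defining the grid.
#' @param counts_peak Expected counts in the parallel-channel peak (1e5 is
#'   typical for anisotropy measurements).
#' @param g Simulated detection-efficiency ratio.
#' @param poisson If `FALSE`, return the noiseless expected curves.
#' @param seed Random seed.
#' @return A list with decay tibbles `parallel` and `perpendicular`.
#' @export
make_polarized_pair <- function(total_model, r0_fast, theta_ns, irf,
                                counts_peak = 1e5, g = 1, poisson = TRUE,
                                seed = NULL) {
  if (abs(r0_fast) > 0.4) abort("`|r0_fast|` must be <= 0.4.")
  stopifnot(theta_ns > 0, g > 0)
  time <- irf$time
  total <- numeric(length(time))
  for (i in seq_along(total_model$lifetimes)) {
    total <- total +
      total_model$amplitudes[i] * exp(-time / total_model$lifetimes[i])
  }
  r_t <- r0_fast * exp(-time / theta_ns)
  kernel <- irf$counts / sum(irf$counts)
  par_exp <- convolve_causal(kernel, total * (1 + 2 * r_t) / 3)
  perp_exp <- convolve_causal(kernel, total * (1 - r_t) / 3)
  scale <- counts_peak / max(par_exp)
  par_exp <- pmax(par_exp * scale, 0)
  perp_exp <- pmax(perp_exp * scale / g, 0)
  if (poisson) {
    counts <- with_seed(seed, {
      list(
        p = rpois(length(par_exp), par_exp),
        q = rpois(length(perp_exp), perp_exp)
      )
    })
  } else {
    counts <- list(p = par_exp, q = perp_exp)
  }
  list(
    parallel = decay_histogram(time, counts$p),
    perpendicular = decay_histogram(time, counts$q)
  )
}

gaussian_band <- function(grid, peak, sigma) exp(-(grid - peak)^2 / (2 * sigma^2))

#' Simulate donor/acceptor reference spectra and a mixture
#'
#' Gaussian-shaped donor and acceptor emission bands (defaults: donor peak
#' 510 nm, sigma 18 nm; acceptor peak 528 nm, sigma 14 nm, emulating a
#' Sapphire-type donor and a Venus-type acceptor on the 5-nm spectral-imaging
#' grid). The mixing weight is solved by bisection on a fine (0.1 nm) grid so
#' that the cumulative donor fraction over `band` equals `band_fraction`.
#'
#' @param band_fraction Target cumulative donor fraction over `band`, in
#'   \[0, 1\].
#' @param band Wavelength band (nm) over which the fraction is evaluated.
#' @param grid Output wavelength grid in nm.
#' @param donor_peak,donor_sigma,acceptor_peak,acceptor_sigma Band shapes
#'   (nm).
#' @param noise_sd Gaussian noise sd added to the mixture, relative to its
#'   peak.
#' @param seed Random seed.
#' @return A list of spectrum tibbles `donor_ref`, `acceptor_ref`, `mixture`,
#'   plus the solved donor coefficient `coeff_donor` (acceptor coefficient
#'   is 1).
#' @export
make_spectra <- function(band_fraction = 0.20, band = c(530, 620),
                         grid = seq(450, 650, by = 5),
                         donor_peak = 510, donor_sigma = 18,
                         acceptor_peak = 528, acceptor_sigma = 14,
                         noise_sd = 0, seed = NULL) {
  if (band_fraction < 0 || band_fraction > 1) {
    abort("`band_fraction` must be in [0, 1].")
  }
  if (length(band) != 2 || band[1] >= band[2] ||
    band[2] <= min(grid) || band[1] >= max(grid)) {
    abort("`band` must be an increasing interval overlapping the wavelength grid.")
  }
  fine <- seq(min(grid), max(grid), by = 0.1)
  d_fine <- gaussian_band(fine, donor_peak, donor_sigma)
  a_fine <- gaussian_band(fine, acceptor_peak, acceptor_sigma)
  band_frac_of <- function(cd) {
    sel <- fine >= band[1] & fine <= band[2]
    num <- pracma::trapz(fine[sel], cd * d_fine[sel])
    den <- pracma::trapz(fine[sel], cd * d_fine[sel] + a_fine[sel])
    num / den
  }
  cd <- if (band_fraction == 0) {
    0
  } else if (band_fraction == 1) {
    abort("A pure-donor band fraction of exactly 1 needs no mixture; use the donor reference.")
  } else {
    # band fraction is monotone in cd; bracket then bisect
    hi <- 1
    while (band_frac_of(hi) < band_fraction) {
      hi <- hi * 2
      if (hi > 1e12) abort("Requested band fraction unreachable for these band shapes.")
    }
    stats::uniroot(function(x) band_frac_of(x) - band_fraction,
      c(0, hi),
      tol = 1e-12
    )$root
  }
  d <- gaussian_band(grid, donor_peak, donor_sigma)
  a <- gaussian_band(grid, acceptor_peak, acceptor_sigma)
  mix <- cd * d + a
  if (noise_sd > 0) {
    mix <- mix + with_seed(seed, rnorm(length(mix), 0, noise_sd * max(mix)))
    mix <- pmax(mix, 0)
  }
  list(
    donor_ref = emission_spectrum(grid, d, "donor"),
    acceptor_ref = emission_spectrum(grid, a, "acceptor"),
    mixture = emission_spectrum(grid, mix, "mixture"),
    coeff_donor = cd
  )
}

#' Simulate an anisotropy Ca2+ titration table
#'
#' Log-spaced free-Ca2+ concentrations with Hill-model anisotropies plus
#' Gaussian noise. Defaults are the high-affinity Cameleon-type sensor
#' calibration (n = 1.9, Kd' = 71 nM, r from 0.10 down to -0.03).
#'
#' @param cal A [hill_calibration()]; default as above.
#' @param n_points Number of titration points.
#' @param conc_range Concentration range in nM (log-spaced).
#' @param sigma_r Gaussian anisotropy noise sd per point.
#' @param seed Random seed.
#' @return A tibble with columns `conc` (nM), `r`, `sigma`.
#' @export
make_titration <- function(cal = hill_calibration(1.9, 71, 0.10, -0.03),
                           n_points = 12, conc_range = c(1, 1e4),
                           sigma_r = 0.003, seed = NULL) {
  conc <- 10^seq(log10(conc_range[1]), log10(conc_range[2]),
    length.out = n_points
  )
  r <- hill_model(conc, cal)
  if (sigma_r > 0) {
    r <- r + with_seed(seed, rnorm(n_points, 0, sigma_r))
  }
  tibble(conc = conc, r = r, sigma = rep(max(sigma_r, 1e-6), n_points))
}

#' Simulate a polarized time-lapse movie of Ca2+-signalling cells
#'
#' Elliptical "cells" on a dark background. Each cell follows a free-Ca2+
#' program (resting level, then a step or sinusoidal oscillation after the
#' stimulus frame), mapped to anisotropy through a Hill calibration. Pixel
#' intensities are split into polarized channels with
#' `I_par = T (1 + 2 r) / 3`, `I_perp = T (1 - r) / 3 / g`, integrated over
#' the frame time, and Poisson-sampled.
#'
#' @param width,height Frame size in pixels.
#' @param n_frames Number of frames.
#' @param frame_interval Frame interval in seconds.
#' @param n_cells Number of cells (placed deterministically from the seed).
#' @param cell_counts Expected total counts per in-cell pixel per frame.
#' @param background_counts Expected background counts per pixel per frame
#'   in each channel.
#' @param cal Hill calibration mapping Ca2+ (nM) to anisotropy.
#' @param ca_rest Resting free Ca2+ in nM (default gives a resting
#'   anisotropy of ~0.10 under the default calibration).
#' @param ca_stim Stimulated free Ca2+ in nM (default gives a stimulated
#'   plateau anisotropy of 0.02).
#' @param stim_frame 0-based frame at which the stimulus arrives (`Inf` for a
#'   resting-only movie).
#' @param program `"step"` (rest then sustained plateau) or `"oscillation"`
#'   (sinusoidal Ca2+ oscillation after the stimulus).
#' @param oscillation_period_s Oscillation period in seconds.
#' @param g,f_corr Simulated correction factors, carried into the stack.
#' @param poisson If `FALSE`, return noiseless expected intensities.
#' @param seed Random seed.
#' @return A list: `stack` ([polarized_stack()]), `rois` (list of 0-based
#'   row-major pixel index vectors per cell), `truth` (tibble of programmed
#'   per-cell `r` and `ca` per frame).
#' @export
make_cell_movie <- function(width = 48, height = 48, n_frames = 40,
                            frame_interval = 1, n_cells = 2,
                            cell_counts = 1000, background_counts = 2,
                            cal = hill_calibration(1.9, 71, 0.10, -0.03),
                            ca_rest = 10, ca_stim = 91, stim_frame = 15,
                            program = c("step", "oscillation"),
                            oscillation_period_s = 20,
                            g = 1, f_corr = 1, poisson = TRUE, seed = NULL) {
  program <- match.arg(program)
  with_seed(seed, {
    # deterministic-from-seed cell geometry on a jittered grid
    centers_x <- width * (seq_len(n_cells) - 0.5) / n_cells +
      stats::runif(n_cells, -width * 0.05, width * 0.05)
    centers_y <- height * 0.5 + stats::runif(n_cells, -height * 0.2, height * 0.2)
    ax <- stats::runif(n_cells, 0.25, 0.4) * width / n_cells
    ay <- stats::runif(n_cells, 0.25, 0.4) * height / 2
    phi <- stats::runif(n_cells, 0, pi)

    masks <- vector("list", n_cells)
    xg <- matrix(rep(seq_len(width), each = height), height, width)
    yg <- matrix(rep(seq_len(height), width), height, width)
    for (i in seq_len(n_cells)) {
      dx <- xg - centers_x[i]
      dy <- yg - centers_y[i]
      u <- dx * cos(phi[i]) + dy * sin(phi[i])
      v <- -dx * sin(phi[i]) + dy * cos(phi[i])
      masks[[i]] <- (u / ax[i])^2 + (v / ay[i])^2 <= 1
    }
    overlap <- Reduce(`+`, lapply(masks, `*`, 1))
    if (any(overlap > 1)) warn("Simulated cells overlap.")

    t_s <- (seq_len(n_frames) - 1) * frame_interval
    stim_t <- stim_frame * frame_interval
    ca_of <- function(t) {
      if (is.infinite(stim_frame) || program == "step") {
        ifelse(t >= stim_t, ca_stim, ca_rest)
      } else {
        ifelse(t >= stim_t,
          ca_rest + (ca_stim - ca_rest) *
            0.5 * (1 - cos(2 * pi * (t - stim_t) / oscillation_period_s)),
          ca_rest
        )
      }
    }

    truth <- list()
    par_arr <- array(0, c(height, width, n_frames))
    perp_arr <- array(0, c(height, width, n_frames))
    for (f in seq_len(n_frames)) {
      total <- matrix(background_counts * 3 / 2, height, width)
      r_map <- matrix(0, height, width)
      for (i in seq_len(n_cells)) {
        ca <- ca_of(t_s[f])
        r_cell <- hill_model(ca, cal)
        total[masks[[i]]] <- cell_counts
        r_map[masks[[i]]] <- r_cell
        truth[[length(truth) + 1]] <- tibble(
          cell = i, frame = f - 1L, time_s = t_s[f], ca = ca, r = r_cell
        )
      }
      par_arr[, , f] <- total * (1 + 2 * r_map) / 3
      perp_arr[, , f] <- total * (1 - r_map) / 3 / g
    }
    if (poisson) {
      par_arr[] <- rpois(length(par_arr), par_arr)
      perp_arr[] <- rpois(length(perp_arr), perp_arr)
    }
    rois <- lapply(masks, function(m) {
      idx <- which(t(m)) - 1L # 0-based row-major
      idx
    })
    list(
      stack = polarized_stack(par_arr, perp_arr,
        frame_interval = frame_interval, g = g, f_corr = f_corr
      ),
      rois = rois,
      truth = dplyr::bind_rows(truth)
    )
  })
}
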