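# Closed-form FRET and photophysical arithmetic.

#' FRET efficiency from amplitude-weighted donor lifetimes
#'
#' `E = 1 - tau_dA / tau_d0`, where `tau_d0` is the amplitude-weighted donor
#' lifetime without acceptor and `tau_dA` with acceptor. A `tau_dA` larger
#' than `tau_d0` yields a negative efficiency with a warning (no FRET).
#'
#' @param tau_d0 Donor-alone amplitude-weighted lifetime (ns), > 0.
#' @param tau_da Donor lifetime in the presence of the acceptor (ns), > 0.
#' @return FRET efficiency as a fraction.
#' @examples
#' fret_efficiency(0.92, 0.22) # 0.761 -> 76%
#' @export
fret_efficiency <- function(tau_d0, tau_da) {
  stopifnot(is.finite(tau_d0), is.finite(tau_da), tau_d0 > 0, tau_da > 0)
  if (any(tau_da > tau_d0)) {
    warn("tau_dA > tau_d0: negative efficiency (no FRET-active pair).")
  }
  1 - tau_da / tau_d0
}

#' FRET transfer time constant
#'
#' `tau_T = 1 / (1/tau_dA - 1/tau_d0)`, the time constant of the energy
#' transfer step. Requires `tau_dA < tau_d0` strictly (positive FRET rate).
#'
#' @inheritParams fret_efficiency
#' @return Transfer time in ns.
#' @examples
#' transfer_time(0.92, 0.22) # 0.289 ns
#' @export
transfer_time <- function(tau_d0, tau_da) {
  stopifnot(is.finite(tau_d0), is.finite(tau_da), tau_d0 > 0, tau_da > 0)
  if (any(tau_da >= tau_d0)) {
    abort("Transfer time undefined: tau_dA must be strictly below tau_d0.")
  }
  1 / (1 / tau_da - 1 / tau_d0)
}

#' Radiative and non-radiative rate constants
#'
#' Decomposes a quantum yield and lifetime into rate constants via
#' `k_r = phi / tau` and `k_nr = 1/tau - k_r`. Lifetimes are given in ns;
#' rates are returned in s^-1.
#'
#' @param phi Fluorescence quantum yield in (0, 1].
#' @param tau_ns Fluorescence lifetime in ns.
#' @return A tibble with columns `phi`, `tau_ns`, `k_r`, `k_nr` (s^-1).
#' @examples
#' rate_constants(0.12, 0.92) # k_r = 1.3e8 s^-1
#' @export
rate_constants <- function(phi, tau_ns) {
  stopifnot(is.finite(phi), is.finite(tau_ns))
  if (any(phi <= 0) || any(phi > 1)) abort("`phi` must be in (0, 1].")
  if (any(tau_ns <= 0)) abort("`tau_ns` must be > 0.")
  k_r <- phi / (tau_ns * 1e-9)
  tibble(phi = phi, tau_ns = tau_ns, k_r = k_r, k_nr = 1 / (tau_ns * 1e-9) - k_r)
}

#' Photophysical context for relative Foerster-distance scaling
#'
#' @param kappa2 Orientation factor, in \[0, 4\].
#' @param refractive_index Medium refractive index, > 0.
#' @param quantum_yield Donor quantum yield, > 0.
#' @param overlap_integral Spectral overlap integral in relative units, > 0.
#' @return A list of class `forster_context`.
#' @export
forster_context <- function(kappa2 = 2 / 3, refractive_index = 1.33,
                            quantum_yield = 1, overlap_integral = 1) {
  stopifnot(
    kappa2 > 0, kappa2 <= 4, refractive_index > 0,
    quantum_yield > 0, overlap_integral > 0
  )
  structure(
    list(
      kappa2 = kappa2, refractive_index = refractive_index,
      quantum_yield = quantum_yield, overlap_integral = overlap_integral
    ),
    class = "forster_context"
  )
}

#' Relative Foerster-distance scale factor
#'
#' Ratio `R0_a / R0_b` between two photophysical contexts, using the
#' one-sixth-power dependence of the Foerster distance on
#' `kappa^2 * n^-4 * Q_D * J`. Only relative scaling is computed; no absolute
#' R0 in distance units.
#'
#' @param context_a,context_b [forster_context()] objects.
#' @return Dimensionless ratio `R0_a / R0_b`.
#' @examples
#' a <- forster_context(quantum_yield = 0.12)
#' b <- forster_context(quantum_yield = 0.64)
#' forster_scale_factor(a, b) # 0.757: a 5.3x dimmer donor shrinks R0 by 24%
#' @export
forster_scale_factor <- function(context_a, context_b) {
  f <- function(ctx) {
    ctx$kappa2 * ctx$refractive_index^-4 * ctx$quantum_yield * ctx$overlap_integral
  }
  (f(context_a) / f(context_b))^(1 / 6)
}

#' FRET rate at a relative donor-acceptor distance
#'
#' `k_T = k_D * (R0 / R)^6` with `k_D` the intrinsic donor decay rate.
#'
#' @param k_d Intrinsic donor excited-state decay rate (any rate unit).
#' @param r Donor-acceptor distance (same relative units as `r0`).
#' @param r0 Foerster distance in the same units.
#' @return FRET rate in the units of `k_d`.
#' @export
fret_rate <- function(k_d, r, r0) {
  stopifnot(k_d > 0, r > 0, r0 > 0)
  k_d * (r0 / r)^6
}

#' Extinction coefficient by the alkaline-denaturation method
#'
#' The chromophore concentration of properly folded protein is read from the
#' denatured absorbance at 447 nm via the reference extinction coefficient
#' 44,000 M^-1 cm^-1, and the native extinction coefficient at 400 nm follows
#' from Beer-Lambert.
#'
#' @param a_native_400 Native absorbance at 400 nm.
#' @param a_denatured_447 Absorbance of the NaOH-denatured sample at 447 nm.
#' @param path_cm Optical path in cm.
#' @param eps_ref Reference extinction coefficient of the denatured
#'   chromophore at 447 nm (M^-1 cm^-1).
#' @return Extinction coefficient at 400 nm in M^-1 cm^-1.
#' @examples
#' extinction_coefficient_alkaline(0.034, 0.044) # 3.4e4
#' @export
extinction_coefficient_alkaline <- function(a_native_400, a_denatured_447,
                                            path_cm = 1, eps_ref = 44000) {
  stopifnot(a_native_400 >= 0, path_cm > 0)
  if (any(a_denatured_447 <= 0)) abort("Denatured absorbance must be > 0.")
  concentration <- a_denatured_447 / (eps_ref * path_cm)
  a_native_400 / (concentration * path_cm)
}

#' Proper-folding ratio
#'
#' Ratio of the chromophore concentration from the alkaline method over the
#' total protein concentration from the theoretical 280 nm extinction
#' coefficient.
#'
#' @param conc_alkaline Folded-protein concentration (M), > 0.
#' @param conc_280nm_theoretical Total protein concentration (M), > 0.
#' @return Fraction of properly folded protein.
#' @export
folding_ratio <- function(conc_alkaline, conc_280nm_theoretical) {
  if (any(conc_280nm_theoretical <= 0) || any(conc_alkaline <= 0)) {
    abort("Concentrations must be > 0.")
  }
  conc_alkaline / conc_280nm_theoretical
}

#' Comparative (relative) quantum yield
#'
#' `phi = phi_ref * I_sample / I_ref` for integrated emission intensities
#' measured at matched optical density.
#'
#' @param integrated_sample Integrated emission intensity of the sample.
#' @param integrated_ref Integrated emission intensity of the reference, > 0.
#' @param phi_ref Quantum yield of the reference.
#' @return Quantum yield of the sample.
#' @examples
#' relative_quantum_yield(0.19, 1, 0.64) # ~0.12
#' @export
relative_quantum_yield <- function(integrated_sample, integrated_ref, phi_ref) {
  stopifnot(integrated_sample >= 0, phi_ref > 0, phi_ref <= 1)
  if (any(integrated_ref <= 0)) abort("Reference integral must be > 0.")
  phi_ref * integrated_sample / integrated_ref
}
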