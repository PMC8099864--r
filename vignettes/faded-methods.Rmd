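---
title: "Methods: anisotropy-based FRET analysis with faded"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anisotropy-based FRET analysis with faded}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faded)
```

This vignette documents the physical models, parameter conventions, and
numerical choices behind each module, in enough detail to audit or reproduce
any number the package emits.

## 1. TCSPC decay fitting by iterative reconvolution

A time-correlated single-photon-counting (TCSPC) histogram records photon
arrival delays on a uniform channel grid. The measured curve is the true
multi-exponential decay convolved with the instrument response function (IRF),
plus a constant background:

$$ y(t) = N \left[\mathrm{IRF} \otimes \sum_i \alpha_i e^{-t/\tau_i}\right](t) + b, \qquad \sum_i \alpha_i = 1 .$$

`fit_decay()` fits this model by Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) with Neyman weights $1/\max(y_k, 1)$, the standard
Poisson approximation for counting data. Free parameters per fit: the
lifetimes $\tau_i$ (optimized as $\log\tau$ to stay positive), the amplitude
fractions (softmax over $n-1$ logits), a sub-channel IRF shift (bounded at
±5 channels), the total intensity ($\log$), and the background.

Conventions and choices:

* **Convolution.** The causal convolution is computed by FFT with zero-padding
  to the next 2–3–5-smooth length. Naive padding to $2n-1$ can land on a prime
  length and degrade the FFT to quadratic cost; the smooth-length pad keeps a
  4096-channel fit in the 0.1–0.3 s range.
* **Half-channel latency.** Both the IRF kernel and the model are sampled at
  channel left edges, so the discrete convolution equals the continuous one
  evaluated half a channel later. This is invisible in practice because the
  shift parameter absorbs it; it only matters when comparing raw curves to
  closed forms (the test suite checks against the exponentially modified
  Gaussian evaluated at $t + \Delta t/2$ and agrees to <0.2%).
* **Reduced chi-square floor.** `reduced_chi_square()` floors the expected
  counts at 1 per channel. Pure Neyman weighting deflates the statistic on
  near-empty tail channels ($E[(O-\mu)^2/\max(O,1)] \approx 0.1$ when
  $\mu \approx 0.1$), which would push long-window fits below the accepted
  [0.8, 1.2] band for purely statistical reasons. The floor is a property of
  the estimator, chosen before any fitting, not a calibration knob.
* **Initialization.** Deterministic: background from the pre-rise channels,
  lifetimes from a log-linear regression on the tail split into segments.
  Identical data therefore always gives identical fits.

Default problem sizes (4096 channels over 20 or 40 ns for cuvette decays,
3125 channels over 50 ns — 16 ps dwell — for polarized microscope traces, IRF
FWHM 0.042 ns, $10^4$ peak counts for lifetime work and $10^5$ for
anisotropy) are this package's choices for realistic working conditions; any
uniform grid is accepted.

## 2. FRET and photophysical arithmetic

All closed forms use amplitude-weighted lifetimes
$\tau = \sum_i \alpha_i \tau_i$ (`amplitude_weighted_lifetime()`):

* FRET efficiency $E = 1 - \tau_{DA}/\tau_{D0}$ and transfer time
  $\tau_T = (1/\tau_{DA} - 1/\tau_{D0})^{-1}$.
* Rate decomposition $k_r = \Phi/\tau$, $k_{nr} = 1/\tau - k_r$
  (`rate_constants()`, lifetimes in ns, rates in s⁻¹).
* Förster-radius scaling
  $R_0 \propto (\kappa^2 n^{-4} Q_D J)^{1/6}$ — `forster_scale_factor()`
  returns ratios only; absolute $R_0$ requires an overlap integral in absolute
  units, which is out of scope.

## 3. Steady-state and time-resolved anisotropy

The polarization-resolved intensities define

$$ r = f_{\mathrm{corr}} \, \frac{I_\parallel - G I_\perp}{I_\parallel + 2 G I_\perp}, $$

where $G$ corrects unequal channel detection efficiency
(`estimate_g_factor()`, e.g. from a magic-angle or free-dye measurement) and
$f_{\mathrm{corr}} \ge 1$ restores anisotropy lost to high-NA depolarization
(`estimate_na_correction()`, the ratio of a reference fluorophore's true to
observed anisotropy). $f_{\mathrm{corr}}$ multiplies the *observed* anisotropy
before any bleed-through compensation: both corrections model instrument
effects on the measured signal, so they are undone first, and compensation of
species mixing happens on instrument-corrected values.

`anisotropy_decay()` builds $r(t)$ channel by channel with first-order Poisson
error propagation

$$ \sigma_r = f_{\mathrm{corr}} \, \frac{3 G \sqrt{I_\perp^2 I_\parallel + I_\parallel^2 I_\perp}}{(I_\parallel + 2 G I_\perp)^2}, $$

masking channels whose summed counts fall below `min_total` (default 20; the
Gaussian error approximation is meaningless below that). The rotational
correlation time comes from a weighted single-exponential tail fit
(`fit_rotational_correlation()`, default `t_start = 5` ns to clear the
IRF and any fast segmental motion); a fitted $\theta$ at the upper bound is
reported as "no decay" rather than a number.

**Perrin conversion and angles.** `perrin_fundamental()` inverts
$r = r_0/(1 + \tau/\theta)$; `angle_from_fundamental()` inverts
$r_0 = 0.4\,(3\cos^2\beta - 1)/2$. The 0.4 prefactor assumes collinear
absorption and emission dipoles of the acceptor itself and single-photon
excitation; if the acceptor's intrinsic fundamental anisotropy is below 0.4,
$\beta$ is biased. This caveat travels with every angle the package reports.

**Bleed-through compensation.** With a fraction $f_d$ of the detected band
intensity coming from the donor (measured by spectral unmixing) at donor
anisotropy $r_d$ (default 0.35, a slowly rotating donor on a large protein),
the observed anisotropy is the intensity-weighted mixture
$r_{\mathrm{obs}} = f_d r_d + (1 - f_d) r_a$, so

$$ r_a = \frac{r_{\mathrm{obs}} - f_d r_d}{1 - f_d} \qquad \texttt{(compensate\_bleed\_through())}. $$

This is an exact algebraic inverse of the mixing model; the test suite checks
the round trip to machine precision over a grid of mixtures.

## 4. Spectral unmixing

`unmix()` solves non-negative least squares
(`pracma::lsqnonneg`) for donor and acceptor coefficients against measured
reference spectra, with an optional signed baseline offset. The donor fraction
in a detection band, `donor_fraction_cumulative()`, is the ratio of trapezoid
band integrals of the fitted components, with linear interpolation at band
edges. No smoothing or baseline modeling beyond the optional constant is
attempted: unmixing is shape-agnostic, and anything fancier belongs upstream.

## 5. Hill calibration of Ca²⁺ sensors

The titration model is the four-parameter Hill function

$$ r(c) = r_{\mathrm{free}} + (r_{\mathrm{bound}} - r_{\mathrm{free}}) \frac{c^n}{K_d'^n + c^n}. $$

`fit_hill()` optimizes $\log n$ and $\log K_d'$ (unit invariance: rescaling
concentrations rescales $K_d'$ exactly), requires at least 5 points spanning a
decade, and seeds from the extreme anisotropies and the mid-response
concentration. `invert_calibration()` is the closed-form inverse; anisotropies
outside the $(r_{\mathrm{bound}}, r_{\mathrm{free}})$ range are clamped to
0 or ∞ with a `"clamped"` attribute and a warning instead of silently
extrapolating.

## 6. Polarized image stacks and IMD rendering

`polarized_stack()` holds parallel/perpendicular stacks as `[height, width,
frame]` arrays. `anisotropy_maps()` applies the pixelwise anisotropy formula
with a summed-count mask (default `min_total = 50`). ROI handling
(`roi_trace()`, `channel_snr()`) uses 0-based row-major pixel indices, the
convention of most imaging toolchains; traces use the ratio-of-sums estimator
(sum intensities over the ROI, then form $r$), which is the minimum-variance
choice for Poisson data, and can be chained through bleed-through
compensation and Hill inversion in one call.

Display processing is deliberately separated from quantification:
`smooth_for_display()` applies a separable x–y–t Gaussian (defaults
$\sigma_{xy} = 0.75$ px, $\sigma_t = 2$ frames, reflective boundaries,
mask-normalized so masked pixels do not bleed in) and optional 2× bilinear
upsampling — for figures and movies only, never before ROI statistics.
`imd_render()` encodes anisotropy as hue over a clipped range (default
[0, 0.12] mapped onto blue→red) with brightness modulated by mean intensity,
the intensity-modulated display convention.

## 7. Synthetic data generators

Every generator takes a `seed` and is fully deterministic given one; defaults
are the working conditions used throughout the documentation and tests.

* `make_irf()`: Gaussian IRF profile, Poisson-sampled counts.
* `make_decay()`: reconvolved multi-exponential scaled to a peak count.
* `make_polarized_pair()`: the total decay is split as
  $I_\parallel = I (1 + 2r(t))/3$, $I_\perp = I (1 - r(t))/3 / G$ with
  $r(t) = r_0 e^{-t/\theta}$ *before* IRF convolution — the definitional
  inverse of the anisotropy formula, so analysis recovers the programmed
  parameters in expectation.
* `make_spectra()`: Gaussian band shapes with the donor coefficient solved
  (bisection on a 0.1 nm quadrature grid) so the donor band fraction hits a
  requested target.
* `make_titration()` and `make_cell_movie()`: Hill-model anisotropies with
  Gaussian noise; movies program per-cell [Ca²⁺] traces (step or oscillation),
  convert them through the calibration, and emit Poisson photon counts plus a
  ground-truth table and ROI masks.

Realism limits are intentional: no dark states, photobleaching, detector
afterpulsing, or vibronic spectral structure. The generators exist to give the
analysis chain a known ground truth, not to emulate hardware.

## Known limitations

* Neyman-weighted least squares, not Poisson maximum likelihood; below ~100
  peak counts a MLE fitter would behave better.
* Single rotational component in the tail fit; segmental + global motion needs
  the `t_start` cut to isolate the slow component.
* The dipole-angle inversion assumes the ideal 0.4 fundamental anisotropy (see
  above).
* The command-line interface (`inst/cli/faded.R`) is a thin wrapper over the
  exported functions — it adds no behavior, so scripted pipelines and
  interactive use cannot drift apart.
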