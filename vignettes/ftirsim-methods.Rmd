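---
title: "Simulating FT-IR imaging data with ftirsim: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating FT-IR imaging data with ftirsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirsim)
```

## Why simulate an FT-IR imaging dataset?

Denoising and preprocessing algorithms for infrared microspectroscopy are
usually judged on measured data, where the "truth" is unknown: every
experimental spectrum carries noise, so one can quantify how much noise an
algorithm removes but not how much *signal* it destroys. `ftirsim` builds a
hyperspectral cube of a simulated tissue core for which the noise-free
reference exists by construction. A denoiser can then be scored both on the
signal-to-noise ratio (SNR) it achieves and on the distortion it introduces
relative to the clean cube.

The pipeline has four stages, run in this order by `run_pipeline()`:

1. **Spectral profiles** — per-pixel randomized sums of Voigt bands
   (`generate_profile()`, `build_clean_cube()`);
2. **Baseline** — a randomized straight-line scattering artifact;
3. **Optical blur** — a wavelength-dependent Gaussian point-spread function
   (`blur_cube()`);
4. **Noise** — absorbance-dependent Gaussian noise calibrated to a target
   SNR series (`scan_series()`).

## Spectral model

Tissue spectra are modelled as mixtures of three biochemical classes —
proteins, nucleic acids (DNA/RNA) and lipids — each represented by a fixed
table of 16 bands (`default_band_table()`): position (cm^-1), width (FWHM,
cm^-1) and per-class area. Band shapes are Voigt profiles, the convolution
of a Gaussian and a Lorentzian, which approximates condensed-phase IR bands
better than either limit alone.

**50/50 mixing.** Each band mixes Gaussian and Lorentzian components of
equal FWHM. The common component width is set with the Olivero–Longbothum
approximation `f_V = 0.5346 f_L + sqrt(0.2166 f_L^2 + f_G^2)` so that the
*total* Voigt FWHM equals the tabulated width; with `f_L = f_G = f` this
gives `f = f_V / 1.63760`. Evaluation uses the Faddeeva function
`w(z) = exp(-z^2) erfc(-iz)`: a Weideman rational approximation (N = 48)
near the band core, a Laplace continued fraction mid-range, and a 4-term
asymptotic series in the far wings. The kernel was validated against direct
quadrature of the Gaussian x Lorentzian convolution to a worst-case relative
error of about 1e-8.

**Randomization.** Biological variability is emulated by re-drawing every
band's position, width and area for every pixel and class independently:
normal distributions with SDs equal to the tabulated percentages of the
nominal values (area SD 5% globally). Widths and areas are clipped below at
1e-6 of nominal so they stay positive. The CO2 band (2352 cm^-1) is special:
its width is never randomized, and its amplitude is spatially white
Uniform(0, 1) — atmospheric absorption has no tissue structure — so it is
excluded from the class profiles during assembly and added once per pixel,
on background pixels too (switchable via `co2_on_background`).

**Area units.** Table areas are interpreted as band integrals per spectral
point of the 4 cm^-1 grid (`area_units = "per_point"`): a band of area `A`
contributes `A * step` in cm^-1 units. This convention puts a
balanced tissue pixel's amide I absorbance near 0.4 after the x10 scaling,
which is what makes the 0.15 tissue-mask threshold meaningful; interpreting
the areas as cm^-1 integrals (`"per_cm"`) would scale all spectra down by
the grid step and leave most tissue below the mask threshold.
`voigt_band()` itself always normalizes in axis units, so its integral
equals its `area` argument exactly.

**Axis.** The default grid descends from 3856 to 800 cm^-1 in 4 cm^-1
steps — exactly 765 points. The upper endpoint is chosen so that a
765-point grid at 4 cm^-1 spans the nominal 3850–900 cm^-1 acquisition
range; both endpoints are configurable.

## Spatial model

The spatial stand-in for a ~1 mm tissue core is a parametric phantom
(`synth_core_maps()`): a centred disc (default radius 56 px at the
desk-scale 128 x 128 grid; 1.1 µm pixels) carrying three smooth random
fields that are softmax-normalized so the class weights sum to exactly 1 on
tissue and are 0 outside. Real class-membership maps come from fuzzy
clustering of measured data; the phantom mimics their qualitative features —
smooth, interlocking protein and nucleic-acid domains and a patchier,
visibly distinct lipid component (shorter correlation length, 3 px vs 8 px)
— while making the ground truth exact. The softmax gain (`sharpness = 3`)
was chosen so that the dominant class membership is typically 0.7–0.95,
matching the fairly crisp memberships fuzzy c-means produces on
well-separated tissue classes. These field parameters are free knobs of the
phantom: nothing in the simulated physics depends on them, but summary
statistics of the absorbance distribution (and hence, e.g., tail-quantile
estimators) do.

The tissue mask uses the inverted coding of the reference data: absorbance
at amide I (1650 cm^-1) strictly above 0.15 marks tissue (0), everything
else background (1).

## Baseline

Scattering grows roughly linearly with wavenumber for tissue sections, so
each pixel receives a straight line `slope * t + intercept` where `t` is the
axis position normalized to [0, 1] from the lowest to the highest
wavenumber. Slope ~ U(0.15, 0.25) and intercept ~ U(-0.00026, 0) are
redrawn per pixel; background pixels get the same line divided by 15. The
normalized-axis abscissa is a design choice: the tabulated slope range only
makes physical sense as an absorbance tilt of ~0.2 across the whole
spectrum, and the tilt must rise toward high wavenumber per the scattering
argument. Spherical-particle (Mie-type) baselines are deliberately out of
scope — they matter for isolated cells, not tissue sections.

## Optical blur

The diffraction-limited spot of a circular aperture is an Airy disc of
first-minimum radius `r = lambda / (2 NA)`. It is approximated by an
isotropic Gaussian with `sigma = 0.341 r` (the package keeps the 34.1%
constant configurable; note that "r covered by three SDs" would give 33.3% —
34.1% is the one-sided one-sigma normal mass and is adopted verbatim as the
calibration constant). Each spectral plane is convolved with its own kernel:
at amide I (lambda ≈ 6 µm, NA 0.5, 1.1 µm pixels) sigma ≈ 1.86 px and the
12 µm Airy extent covers ~11 pixels; at 800 cm^-1 sigma is about twice
that. Convolution uses separable kernels truncated at 4 SD with mirror
(half-sample symmetric) padding, whose effective operator is symmetric and
row-stochastic — so constants are fixed points and every plane's mean is
preserved exactly, avoiding dark rims at the core edge. Blur runs after
baseline insertion, mirroring the acquisition chain the pipeline emulates.

## Noise model and SNR calibration

FT-IR noise has a multiplicative component: the injected noise SD grows
linearly with the clean absorbance, from `sigma_G` at the cube's global
minimum to `1.4 sigma_G` at its maximum (the "40% rule"). The printed
two-equation scaling form that motivates this rule is algebraically
inconsistent (its intercept is quadratic in the noise scale), so the package
implements the stated constraint directly:
`sd(A) = sigma_G * (1 + 0.4 * (A - MIN) / (MAX - MIN))`.

The noise *metric* fits a straight line to the band-free 2150–2075 cm^-1
window (19 points at the default grid), takes absolute residuals, and
reports their sample SD; SNR = 1/noise with unit signal. Two numerical
facts worth knowing:

* For i.i.d. N(0, sigma) noise the estimate's expectation is **not**
  `sigma * sqrt(1 - 2/pi)` (the half-normal SD): the line fit shrinks
  residual variance by (N-2)/N and the sample SD is itself biased, so on 19
  points the expected estimate is ~0.928 of the half-normal value. The
  package keeps the estimator faithful to its printed definition rather
  than bias-correcting it; comparisons across cubes are unaffected because
  the bias is a fixed factor for a fixed window.
* Because the SD field is linear in absorbance, the 40% endpoint excess is
  recovered empirically by `estimate_noise_excess()`: bin the residuals by
  clean absorbance, fit a weighted line through the per-bin SDs, evaluate
  at the observed extremes. SD ratios over the extreme 1% absorbance
  *quantiles* systematically underestimate the endpoint ratio (~28% instead
  of 40% on the default phantom) because the top percentile spans half the
  absorbance range.

`calibrate_sigma()` finds `sigma_G` for a target mean tissue SNR by
bisection on `log(sigma_G)` over [1e-6, 10]. Probes reuse the band-free
window slice of the *same* fixed normal field that the final injection
draws under the given seed, so the re-measured SNR of the emitted cube
equals the converged probe value exactly; convergence tolerance is 1%
relative (default, `tol_rel`). `scan_series()` exploits SNR ∝ sqrt(scans):
each scan count N targets `snr_ref * sqrt(N / scans_ref)`. The default
anchor (`snr_ref = 1000` at 256 scans) is a placeholder of a realistic
order for tissue FT-IR imaging; replace it with the value measured on your
instrument.

## Signal Distortion metric

Given clean, noisy and denoised cubes, `noise_abs = |noisy - clean|` and
`noise_absred = |denoised - noisy|`; the Signal Distortion is
`|noise_absred - noise_abs|` summed over points where
`noise_absred > noise_abs` *strictly* — points where the denoiser moved the
signal further than the noise had. Ties are excluded (a denoiser returning
the noisy or exactly the clean cube scores 0). The package reports the raw
sum over the full cube plus a per-point mean for cross-size comparability;
restricting the sum to a spectral sub-range is left to the caller.

## Problem sizes, numerics, limitations

The desk-scale defaults (128 x 128 x 765, ~100 MB as doubles; 64 x 64 for
calibration studies) run the whole pipeline in well under a minute per
stage and are the sizes used throughout the test-suite and in the package's
own reproduction script. The full-scale 1180 x 1100 grid of the reference
datasets (`full_scale_config()`, ~3 GB cube) is opt-in and needs a machine
with ample RAM.

Degenerate inputs are handled explicitly: a constant cube yields a uniform
noise SD field; a noise-free window reports infinite SNR; a zero-area band
is an exact zero vector; calibration warns and returns its best iterate if
the bracket cannot meet the tolerance.

What passing tests show — and what they do not: the suite verifies the
simulation's internal physics (line shapes against quadrature, blur moments,
noise laws, calibration closure) on the phantom. Real tissue data differ in
ways the phantom does not model: more than three biochemical classes,
non-Gaussian membership fields, Mie-type baselines for cellular samples,
detector drift, and interferogram-domain noise correlations. Results on
`ftirsim` cubes therefore bound an algorithm's behaviour under known,
idealized conditions; they do not certify performance on measured data.

## ENVI I/O

Cubes are exchanged as ENVI pairs (raw BSQ binary + text header), readable
by standard hyperspectral viewers: float32 by default, float64 for lossless
round trips. The header carries the wavenumber list and the cube's stage
and seed, so `read_cube()` restores provenance. The pipeline manifest
(JSON) records the configuration and every derived seed; a run is
regenerable bit-exactly from it.
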