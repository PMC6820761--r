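# Voigt line shapes via the Faddeeva function (compiled kernel in src/).

# Total Voigt FWHM for equal Gaussian/Lorentzian component FWHM f:
# f_V = 0.5346 f + sqrt(0.2166 f^2 + f^2) (Olivero-Longbothum), so
# f = f_V / OL_EQUAL.
OL_EQUAL <- 0.5346 + sqrt(1.2166)

# Gaussian FWHM -> SD
FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Voigt component widths for a 50/50 Gaussian-Lorentzian band
#'
#' The band model mixes equal-width Gaussian and Lorentzian components; the
#' common component FWHM is chosen with the Olivero-Longbothum approximation
#' so that the total Voigt FWHM equals the requested width.
#'
#' @param fwhm total Voigt FWHM (cm^-1), positive.
#' @return A list with `sigma` (Gaussian SD) and `gamma` (Lorentzian HWHM),
#'   both in cm^-1.
#' @export
voigt_widths <- function(fwhm) {
  if (any(!is.finite(fwhm)) || any(fwhm <= 0))
    stop("`fwhm` must be positive", call. = FALSE)
  fc <- fwhm / OL_EQUAL
  list(sigma = fc * FWHM_TO_SIGMA, gamma = fc / 2)
}

#' Evaluate one Voigt band on a spectral axis
#'
#' The line shape is the convolution of a Gaussian and a Lorentzian of equal
#' FWHM (a "50% Gaussian / 50% Lorentzian" band), with the component width set
#' so the total FWHM equals `fwhm`, evaluated with the Faddeeva (complex error)
#' function. The analytic integral of the returned curve over the whole real
#' line equals `area` (axis units, cm^-1).
#'
#' @param axis a [make_axis()] grid (or any numeric vector of wavenumbers).
#' @param center band position (cm^-1).
#' @param fwhm total band FWHM (cm^-1), positive.
#' @param area band area (integral in cm^-1 units), non-negative.
#' @return Numeric vector of intensities aligned with `axis`.
#' @examples
#' ax <- make_axis()
#' band <- voigt_band(ax, 1650, 42, 1)
#' @export
voigt_band <- function(axis, center, fwhm, area) {
  if (!is.finite(area) || area < 0) stop("`area` must be >= 0", call. = FALSE)
  w <- voigt_widths(fwhm)
  .voigt_sum_cpp(as.numeric(axis), center, w$sigma, w$gamma, area)
}

# Sum of area-scaled Voigt bands with per-band total FWHM (vectorized kernel).
voigt_sum <- function(axis, centers, fwhms, areas) {
  w <- voigt_widths(fwhms)
  .voigt_sum_cpp(as.numeric(axis), centers, w$sigma, w$gamma, areas)
}

# Re(w(z)) on the upper half-plane; exposed for validation against
# independent quadrature.
faddeeva_re <- function(z) {
  .faddeeva_re_cpp(Re(z), Im(z))
}
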