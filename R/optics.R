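# Wavelength-dependent spatial blur: the diffraction-limited Airy disc is
# approximated by an isotropic Gaussian whose SD is a fixed fraction of the
# Airy radius, converted to pixels and applied plane by plane.

#' Optics configuration
#'
#' @param numerical_aperture objective NA (dimensionless, in (0, 1.5]).
#' @param pixel_pitch_um projected pixel size (um).
#' @param sigma_fraction Gaussian SD as a fraction of the Airy radius.
#' @param trunc_sd kernel truncation, in SD multiples.
#' @return A list of class `"optics_config"`.
#' @export
optics_config <- function(numerical_aperture = 0.5, pixel_pitch_um = 1.1,
                          sigma_fraction = 0.341, trunc_sd = 4) {
  if (numerical_aperture <= 0 || numerical_aperture > 1.5)
    stop("`numerical_aperture` must be in (0, 1.5]", call. = FALSE)
  if (pixel_pitch_um <= 0) stop("`pixel_pitch_um` must be positive", call. = FALSE)
  if (sigma_fraction <= 0) stop("`sigma_fraction` must be positive", call. = FALSE)
  structure(list(numerical_aperture = numerical_aperture,
                 pixel_pitch_um = pixel_pitch_um,
                 sigma_fraction = sigma_fraction,
                 trunc_sd = trunc_sd),
            class = "optics_config")
}

#' Airy disc radius
#'
#' First-minimum radius of the diffraction pattern of a circular aperture,
#' `r = lambda / (2 NA)` (equivalently `1.22 lambda R / a` with
#' `R = a / (2.44 NA)`).
#'
#' @param wavelength_um wavelength in um, positive.
#' @param na numerical aperture, positive.
#' @return radius in um.
#' @examples
#' airy_radius(6, 0.5) # 6 um, i.e. a 12 um total extent
#' @export
airy_radius <- function(wavelength_um, na) {
  if (any(wavelength_um <= 0) || any(na <= 0))
    stop("wavelength and NA must be positive", call. = FALSE)
  wavelength_um / (2 * na)
}

#' Gaussian blur SD from the Airy radius
#'
#' @param r Airy radius (um), positive.
#' @param sigma_fraction fraction of `r` (default 0.341, the package's
#'   Airy-to-Gaussian calibration).
#' @return SD in um.
#' @examples
#' blur_sigma(airy_radius(6, 0.5)) # 2.046 um
#' @export
blur_sigma <- function(r, sigma_fraction = 0.341) {
  if (any(r <= 0)) stop("`r` must be positive", call. = FALSE)
  sigma_fraction * r
}

#' Per-plane blur SDs in pixels
#'
#' @param axis a [make_axis()] grid.
#' @param cfg an [optics_config()].
#' @return Numeric vector of Gaussian SDs (px), one per axis point.
#' @export
plane_sigmas <- function(axis, cfg = optics_config()) {
  lam <- wavenumber_to_wavelength(as.numeric(axis))
  blur_sigma(airy_radius(lam, cfg$numerical_aperture), cfg$sigma_fraction) /
    cfg$pixel_pitch_um
}

# Separable Gaussian convolution of one plane with half-sample symmetric
# (mirror) padding; the effective operator is symmetric and row-stochastic,
# so a constant plane and the plane mean are preserved.
gauss_blur_plane <- function(m, sigma_px, trunc_sd = 4) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, as.integer(ceiling(trunc_sd * sigma_px)))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma_px)
  k <- k / sum(k)
  t(conv_sym(t(conv_sym(m, k, r)), k, r))
}

conv_sym <- function(m, k, r) {
  n <- nrow(m)
  idx <- c(pmin.int(r:1, n), seq_len(n), pmax.int(n - seq_len(r) + 1L, 1L))
  out <- stats::filter(m[idx, , drop = FALSE], k, method = "convolution", sides = 2)
  matrix(out[(r + 1L):(r + n), ], n, ncol(m))
}

#' Apply the wavelength-dependent point-spread blur to a cube
#'
#' Each spectral plane is convolved with an isotropic 2-D Gaussian whose SD
#' (in pixels) is `sigma_fraction * (1e4/wn) / (2 NA) / pixel_pitch`, so blur
#' grows toward low wavenumbers (long wavelengths). Mirror boundary handling
#' preserves each plane's mean.
#'
#' @param cube an [ftir_cube()] (at least 3 x 3 pixels).
#' @param cfg an [optics_config()].
#' @return A new cube with stage `"clean"`.
#' @export
blur_cube <- function(cube, cfg = optics_config()) {
  d <- cube_dims(cube)
  if (d[1L] < 3L || d[2L] < 3L)
    stop("cube must have at least 3 x 3 spatial extent", call. = FALSE)
  sig <- plane_sigmas(cube$axis, cfg)
  out <- cube$data
  for (k in seq_len(d[3L]))
    out[, , k] <- gauss_blur_plane(cube$data[, , k], sig[k], cfg$trunc_sd)
  meta <- cube$meta
  meta$optics <- cfg[c("numerical_aperture", "pixel_pitch_um", "sigma_fraction")]
  ftir_cube(out, cube$axis, stage = "clean", meta = meta)
}
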