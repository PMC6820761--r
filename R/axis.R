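#' Build a descending wavenumber axis
#'
#' FT-IR spectra are indexed on a uniform, strictly descending wavenumber grid
#' (cm^-1). The default grid, 3856 to 800 cm^-1 in 4 cm^-1 steps, has exactly
#' 765 points and matches the spectral dimension of the reference datasets.
#'
#' @param max_wn highest wavenumber (cm^-1), first axis point.
#' @param min_wn lowest wavenumber (cm^-1); the grid steps down from `max_wn`
#'   and stops at the last point `>= min_wn`.
#' @param step grid spacing (cm^-1), positive.
#' @return A numeric vector of class `"spectral_axis"`, strictly descending,
#'   with attribute `step`.
#' @examples
#' ax <- make_axis()
#' length(ax) # 765
#' @export
make_axis <- function(max_wn = 3856, min_wn = 800, step = 4) {
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0)
    stop("`step` must be a positive number", call. = FALSE)
  if (!is.numeric(max_wn) || !is.numeric(min_wn) || max_wn <= min_wn)
    stop("`max_wn` must exceed `min_wn`", call. = FALSE)
  wn <- seq(max_wn, min_wn, by = -step)
  structure(as.numeric(wn), class = "spectral_axis", step = step)
}

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %d points, %.9g to %.9g cm^-1, step %.9g cm^-1\n",
              length(x), x[1L], x[length(x)], attr(x, "step")))
  invisible(x)
}

axis_step <- function(axis) {
  st <- attr(axis, "step")
  if (is.null(st)) st <- abs(axis[1L] - axis[2L])
  st
}

as_spectral_axis <- function(x, step = NULL) {
  if (inherits(x, "spectral_axis")) return(x)
  x <- as.numeric(x)
  d <- diff(x)
  if (length(x) < 2L || any(d >= 0) || max(abs(d - d[1L])) > 1e-9)
    stop("axis must be uniformly spaced and strictly descending", call. = FALSE)
  structure(x, class = "spectral_axis", step = if (is.null(step)) -d[1L] else step)
}

#' Convert wavenumber to wavelength
#'
#' `lambda(um) = 1e4 / nu(cm^-1)`; e.g. the amide I band at 1650 cm^-1
#' corresponds to a wavelength of about 6 um.
#'
#' @param wn wavenumber(s) in cm^-1, strictly positive.
#' @return wavelength(s) in micrometres.
#' @export
wavenumber_to_wavelength <- function(wn) {
  if (!is.numeric(wn) || any(!is.finite(wn)) || any(wn <= 0))
    stop("wavenumbers must be positive and finite", call. = FALSE)
  1e4 / wn
}
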