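# The hyperspectral cube container: rows x cols x bands absorbance array plus
# its wavenumber axis and provenance metadata.

#' Construct a hyperspectral cube
#'
#' @param data numeric array `rows x cols x n_points` of absorbance.
#' @param axis a [make_axis()] grid; its length must match `dim(data)[3]`.
#' @param stage processing stage tag, normally one of `"clean_preblur"`,
#'   `"clean"`, `"noisy"`, `"denoised"`; unknown tags are preserved verbatim.
#' @param meta named list of provenance fields (seed, config, ...).
#' @return An object of class `"ftir_cube"`: a list with elements `data`,
#'   `axis` and `meta` (which carries `stage`).
#' @export
ftir_cube <- function(data, axis, stage = "clean", meta = list()) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (rows x cols x bands)", call. = FALSE)
  axis <- as_spectral_axis(axis)
  if (dim(data)[3L] != length(axis))
    stop("third dimension of `data` (", dim(data)[3L],
         ") must equal the axis length (", length(axis), ")", call. = FALSE)
  if (any(!is.finite(data)))
    stop("cube values must be finite", call. = FALSE)
  meta$stage <- stage
  structure(list(data = data, axis = axis, meta = meta), class = "ftir_cube")
}

#' @export
print.ftir_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ftir_cube> %d x %d pixels x %d points [stage: %s]\n",
              d[1L], d[2L], d[3L], x$meta$stage %||% "?"))
  cat(sprintf("  axis: %.9g to %.9g cm^-1; absorbance range [%.4g, %.4g]\n",
              x$axis[1L], x$axis[length(x$axis)], min(x$data), max(x$data)))
  invisible(x)
}

cube_dims <- function(cube) dim(cube$data)

stopifnot_same_shape <- function(...) {
  cubes <- list(...)
  d <- lapply(cubes, function(cb) dim(cb$data))
  if (!all(vapply(d[-1], identical, logical(1), d[[1]])))
    stop("cubes must share the same dimensions", call. = FALSE)
  ax <- lapply(cubes, function(cb) as.numeric(cb$axis))
  if (!all(vapply(ax[-1], function(a) isTRUE(all.equal(a, ax[[1]])), logical(1))))
    stop("cubes must share the same spectral axis", call. = FALSE)
  invisible(TRUE)
}

# Index of the axis point nearest to a target wavenumber; errors when the
# target falls outside the axis range.
nearest_band <- function(axis, wn) {
  if (wn > max(axis) || wn < min(axis))
    stop("wavenumber ", wn, " cm^-1 lies outside the axis range [",
         min(axis), ", ", max(axis), "]", call. = FALSE)
  which.min(abs(as.numeric(axis) - wn))
}

# Small non-cryptographic config fingerprint (polynomial hash of the
# deparsed value).
config_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = " "))
  h <- 0
  for (ch in s) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
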