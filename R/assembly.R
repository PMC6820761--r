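# Cube assembly: per-pixel randomized class profiles weighted by the
# concentration maps, the x10 absorbance scaling, the spatially random CO2
# band, and the randomized linear scattering baseline.

#' Draw random baseline coefficients
#'
#' Scattering tilts tissue spectra roughly linearly in wavenumber; slope and
#' intercept are drawn uniformly from the calibrated ranges (slope 0.15-0.25
#' absorbance across the axis, intercept -0.00026-0).
#'
#' @param n number of draws.
#' @return A list with numeric `slope` and `intercept` (length `n`).
#' @export
sample_baseline <- function(n = 1) {
  list(slope = stats::runif(n, 0.15, 0.25),
       intercept = stats::runif(n, -0.00026, 0))
}

#' Evaluate a straight-line baseline on an axis
#'
#' The abscissa is the axis position normalized to \[0, 1\] from the lowest to
#' the highest wavenumber, so the baseline rises toward high wavenumbers as
#' scattering does. Background pixels see the same line divided by
#' `background_divisor` (weak scattering without a sample).
#'
#' @param axis a [make_axis()] grid.
#' @param params list with `slope` and `intercept` (see [sample_baseline()]).
#' @param is_background logical.
#' @param background_divisor attenuation factor for background pixels.
#' @return Numeric vector aligned with `axis`.
#' @export
baseline_vector <- function(axis, params, is_background = FALSE,
                            background_divisor = 15) {
  wn <- as.numeric(axis)
  t <- (wn - min(wn)) / (max(wn) - min(wn))
  b <- params$slope * t + params$intercept
  if (is_background) b <- b / background_divisor
  b
}

#' Assemble the pre-blur clean cube
#'
#' For every tissue pixel, three freshly randomized class profiles are summed
#' with the pixel's concentration weights, the CO2 band is added with the
#' pixel's random amplitude, the result is multiplied by `absorbance_scale`,
#' and an independently drawn linear baseline is added. Background pixels get
#' the attenuated baseline (and, by default, the CO2 band, since atmospheric
#' CO2 is sample-independent) but no class bands.
#'
#' @param maps a [synth_core_maps()] object.
#' @param table a [read_band_table()] table.
#' @param axis a [make_axis()] grid.
#' @param seed optional integer seed recorded in the cube metadata.
#' @param absorbance_scale multiplicative scale applied to all band content.
#' @param baseline logical; disable to get pure band content.
#' @param randomize logical; disable band randomization (nominal parameters).
#' @param co2_map `rows x cols` amplitude matrix (see [synth_co2_map()]),
#'   `NULL` to draw one internally, or `FALSE` to omit the CO2 band.
#' @param co2_on_background include the CO2 band on background pixels.
#' @param background_divisor baseline attenuation for background pixels.
#' @param area_units see [generate_profile()].
#' @return An [ftir_cube()] with stage `"clean_preblur"`.
#' @export
build_clean_cube <- function(maps, table = default_band_table(),
                             axis = make_axis(), seed = NULL,
                             absorbance_scale = 10, baseline = TRUE,
                             randomize = TRUE, co2_map = NULL,
                             co2_on_background = TRUE,
                             background_divisor = 15,
                             area_units = c("per_point", "per_cm")) {
  area_units <- match.arg(area_units)
  rows <- maps$shape[1L]
  cols <- maps$shape[2L]
  if (!is.null(seed)) set.seed(seed)
  use_co2 <- !isFALSE(co2_map)
  if (use_co2 && is.null(co2_map)) co2_map <- synth_co2_map(rows, cols)
  if (use_co2 && !all(dim(co2_map) == c(rows, cols)))
    stop("`co2_map` dimensions must match the concentration maps", call. = FALSE)

  n <- length(axis)
  scale <- if (area_units == "per_point") axis_step(axis) else 1
  tab_classes <- table[table$center_cm1 != CO2_CENTER, , drop = FALSE]
  co2_row <- table[table$center_cm1 == CO2_CENTER, , drop = FALSE]
  area_sd <- attr(table, "area_sd_pct") %||% AREA_SD_PCT

  spec <- matrix(0, n, rows * cols)
  ax <- as.numeric(axis)
  for (j in seq_len(cols)) {
    for (i in seq_len(rows)) {
      px <- (j - 1L) * rows + i
      y <- numeric(n)
      if (maps$core[i, j]) {
        for (cl in CLASS_IDS) {
          w <- maps$class_maps[[cl]][i, j]
          if (w <= 0) next
          rb <- if (randomize) randomize_bands(tab_classes, cl) else
            list(center = tab_classes$center_cm1, fwhm = tab_classes$fwhm_cm1,
                 area = tab_classes[[area_column(cl)]])
          y <- y + voigt_sum(ax, rb$center, rb$fwhm, w * rb$area * scale)
        }
      }
      if (use_co2 && nrow(co2_row) &&
          (maps$core[i, j] || co2_on_background)) {
        amp <- co2_map[i, j]
        if (amp > 0) {
          if (randomize) {
            rb <- randomize_band(co2_row, "protein", area_sd_pct = area_sd)
          } else {
            rb <- list(center = co2_row$center_cm1, fwhm = co2_row$fwhm_cm1,
                       area = co2_row$area_protein)
          }
          y <- y + voigt_sum(ax, rb$center, rb$fwhm, amp * rb$area * scale)
        }
      }
      y <- y * absorbance_scale
      if (baseline) {
        bp <- sample_baseline()
        y <- y + baseline_vector(axis, bp, is_background = !maps$core[i, j],
                                 background_divisor = background_divisor)
      }
      spec[, px] <- y
    }
  }
  data <- aperm(array(spec, c(n, rows, cols)), c(2, 3, 1))
  cfg <- list(rows = rows, cols = cols, absorbance_scale = absorbance_scale,
              baseline = baseline, randomize = randomize,
              co2_on_background = co2_on_background,
              background_divisor = background_divisor, area_units = area_units)
  ftir_cube(data, axis, stage = "clean_preblur",
            meta = list(seed = seed, config = cfg, config_hash = config_hash(cfg)))
}
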