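# The band table: 16 IR bands with per-class areas and randomization SDs.
# Ships as inst/extdata/band_table.csv; users may supply their own file with
# the same columns.

CLASS_IDS <- c("dna_rna", "protein", "lipid")
CO2_CENTER <- 2352
AREA_SD_PCT <- 5 # global area randomization (percent of nominal)

#' Read a band parameter table
#'
#' Columns: `center_cm1`, `center_sd_pct`, `fwhm_cm1`, `fwhm_sd_pct` (empty =
#' width never randomized, as for the atmospheric CO2 band at 2352 cm^-1),
#' `area_dna_rna`, `area_protein`, `area_lipid`. Areas are band integrals per
#' spectral point of the default 4 cm^-1 grid (see [generate_profile()]).
#'
#' @param path CSV file path.
#' @param area_sd_pct global SD of area randomization, percent of nominal.
#' @return A `data.frame` of class `"band_table"` with attribute
#'   `area_sd_pct`.
#' @export
read_band_table <- function(path, area_sd_pct = AREA_SD_PCT) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_band_table(tab)
  structure(tab, class = c("band_table", "data.frame"), area_sd_pct = area_sd_pct)
}

#' The packaged 16-band table
#'
#' @inheritParams read_band_table
#' @return See [read_band_table()].
#' @examples
#' tab <- default_band_table()
#' nrow(tab) # 16
#' @export
default_band_table <- function(area_sd_pct = AREA_SD_PCT) {
  read_band_table(system.file("extdata", "band_table.csv", package = "ftirsim",
                              mustWork = TRUE),
                  area_sd_pct = area_sd_pct)
}

validate_band_table <- function(tab) {
  need <- c("center_cm1", "center_sd_pct", "fwhm_cm1", "fwhm_sd_pct",
            "area_dna_rna", "area_protein", "area_lipid")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("band table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(tab$fwhm_cm1 <= 0)) stop("band widths must be positive", call. = FALSE)
  areas <- as.matrix(tab[, paste0("area_", CLASS_IDS)])
  if (any(areas < 0)) stop("band areas must be non-negative", call. = FALSE)
  invisible(tab)
}

area_column <- function(class_id) {
  class_id <- match.arg(class_id, CLASS_IDS)
  paste0("area_", class_id)
}

#' Randomize one band's parameters
#'
#' Draws a realization of a band: position and width from normal distributions
#' whose SDs are the stated percentages of the nominal values (width untouched
#' when its SD column is empty, as for the CO2 band), and area from a normal
#' with the table's global SD (default 5%). Width and area are clipped below
#' at 1e-6 of nominal so they stay positive.
#'
#' @param spec one row of a [read_band_table()] table (a list or 1-row
#'   data.frame).
#' @param class_id one of `"dna_rna"`, `"protein"`, `"lipid"`.
#' @param area_sd_pct SD of area randomization, percent of nominal.
#' @return A list with realized `center`, `fwhm`, `area`.
#' @export
randomize_band <- function(spec, class_id, area_sd_pct = AREA_SD_PCT) {
  area0 <- spec[[area_column(class_id)]]
  center <- stats::rnorm(1, spec$center_cm1, spec$center_sd_pct / 100 * spec$center_cm1)
  fwhm <- if (is.na(spec$fwhm_sd_pct)) spec$fwhm_cm1 else
    stats::rnorm(1, spec$fwhm_cm1, spec$fwhm_sd_pct / 100 * spec$fwhm_cm1)
  area <- stats::rnorm(1, area0, area_sd_pct / 100 * area0)
  list(center = center,
       fwhm = max(fwhm, 1e-6 * spec$fwhm_cm1),
       area = max(area, 1e-6 * area0))
}

# Vectorized randomization of a whole table for one class. Draw order
# (centers, widths, areas) is fixed so results are seed-reproducible.
randomize_bands <- function(tab, class_id) {
  n <- nrow(tab)
  area0 <- tab[[area_column(class_id)]]
  area_sd_pct <- attr(tab, "area_sd_pct") %||% AREA_SD_PCT
  center <- stats::rnorm(n, tab$center_cm1, tab$center_sd_pct / 100 * tab$center_cm1)
  fwhm_sd <- ifelse(is.na(tab$fwhm_sd_pct), 0, tab$fwhm_sd_pct) / 100 * tab$fwhm_cm1
  fwhm <- stats::rnorm(n, tab$fwhm_cm1, fwhm_sd)
  fwhm[is.na(tab$fwhm_sd_pct)] <- tab$fwhm_cm1[is.na(tab$fwhm_sd_pct)]
  area <- stats::rnorm(n, area0, area_sd_pct / 100 * area0)
  list(center = center,
       fwhm = pmax(fwhm, 1e-6 * tab$fwhm_cm1),
       area = pmax(area, 1e-6 * area0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate one randomized class profile
#'
#' A profile is the sum of the table's Voigt bands with the class's areas,
#' each band independently randomized (see [randomize_band()]). Table areas
#' are band integrals per spectral point: on a grid with step `s` cm^-1 an
#' area `A` contributes `A * s` in cm^-1 units (`area_units = "per_point"`,
#' the default, matching the absorbance scale of the reference datasets);
#' `"per_cm"` uses the areas as cm^-1 integrals directly.
#'
#' @param class_id `"dna_rna"`, `"protein"` or `"lipid"`.
#' @param table a [read_band_table()] table.
#' @param axis a [make_axis()] grid.
#' @param randomize logical; `FALSE` evaluates the nominal (mean) parameters.
#' @param include_co2 logical; drop the 2352 cm^-1 CO2 band when `FALSE`
#'   (its amplitude is spatially random and is added separately during cube
#'   assembly).
#' @param area_units `"per_point"` or `"per_cm"`.
#' @return Numeric intensity vector aligned with `axis`, with attribute
#'   `class_id`.
#' @examples
#' set.seed(1)
#' p <- generate_profile("protein", default_band_table(), make_axis())
#' @export
generate_profile <- function(class_id, table = default_band_table(),
                             axis = make_axis(), randomize = TRUE,
                             include_co2 = TRUE,
                             area_units = c("per_point", "per_cm")) {
  class_id <- match.arg(class_id, CLASS_IDS)
  area_units <- match.arg(area_units)
  tab <- table
  if (!include_co2) tab <- tab[tab$center_cm1 != CO2_CENTER, , drop = FALSE]
  if (randomize) {
    rb <- randomize_bands(tab, class_id)
  } else {
    rb <- list(center = tab$center_cm1, fwhm = tab$fwhm_cm1,
               area = tab[[area_column(class_id)]])
  }
  scale <- if (area_units == "per_point") axis_step(axis) else 1
  y <- voigt_sum(axis, rb$center, rb$fwhm, rb$area * scale)
  structure(y, class_id = class_id)
}
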