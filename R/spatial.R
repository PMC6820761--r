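# Synthetic spatial structure: a circular tissue core carrying three smooth
# class-concentration fields (a parametric stand-in for fuzzy-clustering
# membership maps), a spatially white CO2 amplitude map, and the
# absorbance-threshold tissue mask.

#' Synthesize class-concentration maps for a circular tissue core
#'
#' Inside a centred circular core, three spatially smooth random fields are
#' drawn (Gaussian-smoothed white noise, standardized and passed through a
#' softmax) so the three class weights sum to exactly 1 per pixel. The lipid
#' field uses its own, shorter correlation length, so it forms a visibly
#' patchier pattern than the two chromatin/protein-like classes. Outside the
#' core all weights are 0.
#'
#' @param rows,cols grid size in pixels.
#' @param core_radius_px core radius in pixels; must fit inside the frame.
#' @param smoothness_px Gaussian correlation scale (SD, px) of the DNA/RNA and
#'   protein fields.
#' @param lipid_smoothness_px correlation scale (px) of the lipid field.
#' @param sharpness softmax gain; larger values give crisper, more
#'   cluster-like memberships (dominant class weight near 1), smaller values
#'   fuzzier mixtures.
#' @param seed optional integer seed.
#' @return An object of class `"conc_maps"`: list with `class_maps` (named
#'   list of `dna_rna`, `protein`, `lipid` matrices), `core` (logical matrix),
#'   and `shape`.
#' @export
synth_core_maps <- function(rows = 128, cols = 128, core_radius_px = 56,
                            smoothness_px = 8, lipid_smoothness_px = 3,
                            sharpness = 3, seed = NULL) {
  if (rows <= 0 || cols <= 0) stop("grid dimensions must be positive", call. = FALSE)
  if (core_radius_px <= 0 || core_radius_px > min(rows, cols) / 2)
    stop("`core_radius_px` must be in (0, min(rows, cols)/2]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cx <- (rows + 1) / 2
  cy <- (cols + 1) / 2
  dist2 <- outer((seq_len(rows) - cx)^2, (seq_len(cols) - cy)^2, `+`)
  core <- dist2 <= core_radius_px^2

  smooth_field <- function(sig) {
    f <- gauss_blur_plane(matrix(stats::rnorm(rows * cols), rows, cols), sig)
    v <- f[core]
    f[core] <- (v - mean(v)) / stats::sd(v)
    f
  }
  fields <- list(dna_rna = smooth_field(smoothness_px),
                 protein = smooth_field(smoothness_px),
                 lipid = smooth_field(lipid_smoothness_px))
  ex <- lapply(fields, function(f) exp(sharpness * f))
  tot <- ex$dna_rna + ex$protein + ex$lipid
  class_maps <- lapply(ex, function(e) {
    w <- e / tot
    w[!core] <- 0
    w
  })
  structure(list(class_maps = class_maps, core = core, shape = c(rows, cols)),
            class = "conc_maps")
}

#' @export
print.conc_maps <- function(x, ...) {
  cat(sprintf("<conc_maps> %d x %d px, %d core (tissue) pixels\n",
              x$shape[1L], x$shape[2L], sum(x$core)))
  invisible(x)
}

#' Spatially random CO2 amplitude map
#'
#' Atmospheric CO2 absorption is unrelated to the tissue structure: its
#' per-pixel amplitude is i.i.d. Uniform(0, 1) everywhere, with no smoothing
#' and no tissue masking.
#'
#' @inheritParams synth_core_maps
#' @return A `rows x cols` matrix of weights in \[0, 1\].
#' @export
synth_co2_map <- function(rows = 128, cols = 128, seed = NULL) {
  if (rows <= 0 || cols <= 0) stop("grid dimensions must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(rows * cols), rows, cols)
}

#' Threshold-based tissue mask
#'
#' A pixel is tissue when its absorbance at the selected band (nearest axis
#' point to `band_wn`, amide I by default) exceeds `threshold`. The mask uses
#' the inverted coding of the reference datasets: 0 = tissue, 1 = background.
#'
#' @param cube an [ftir_cube()].
#' @param threshold absorbance threshold (strictly above = tissue).
#' @param band_wn wavenumber (cm^-1) of the thresholding band; must lie
#'   within the axis range.
#' @return An integer matrix of class `"tissue_mask"` (0 tissue, 1 background).
#' @export
build_mask <- function(cube, threshold = 0.15, band_wn = 1650) {
  k <- nearest_band(cube$axis, band_wn)
  m <- ifelse(cube$data[, , k] > threshold, 0L, 1L)
  structure(m, class = c("tissue_mask", class(m)))
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("<tissue_mask> %d x %d px, %d tissue / %d background\n",
              nrow(x), ncol(x), sum(x == 0L), sum(x == 1L)))
  invisible(x)
}
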