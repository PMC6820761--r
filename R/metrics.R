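# Denoising benchmark metrics against the known clean reference.

#' Signal Distortion of a denoised cube
#'
#' With `noise_abs = |noisy - clean|` (noise originally introduced) and
#' `noise_absred = |denoised - noisy|` (change made by the denoiser), the
#' Signal Distortion at a data point is `|noise_absred - noise_abs|`, summed
#' only over points where `noise_absred > noise_abs` (strictly): points where
#' the denoiser moved the signal further than the original noise displaced
#' it. Points at exact equality are excluded.
#'
#' @param clean,noisy,denoised [ftir_cube()] objects sharing shape and axis.
#' @param per_pixel also return a per-pixel map of the summed distortion.
#' @return A list of class `"distortion_report"`: `sd_total` (raw absorbance
#'   sum), `sd_mean` (per data point, for cross-size comparability),
#'   `n_flagged`, `n_total`, and optionally `per_pixel_sd`.
#' @examples
#' ax <- make_axis(108, 100, 4)
#' z <- array(0, c(2, 2, 3))
#' clean <- ftir_cube(z, ax)
#' noisy <- ftir_cube(z + 1, ax, stage = "noisy")
#' den <- ftir_cube(z - 1, ax, stage = "denoised")
#' signal_distortion(clean, noisy, den)$sd_total # 12 points, each SD 1
#' @export
signal_distortion <- function(clean, noisy, denoised, per_pixel = FALSE) {
  stopifnot_same_shape(clean, noisy, denoised)
  na_ <- abs(noisy$data - clean$data)
  nr <- abs(denoised$data - noisy$data)
  flag <- nr > na_
  sd_pt <- ifelse(flag, abs(nr - na_), 0)
  out <- list(sd_total = sum(sd_pt),
              sd_mean = sum(sd_pt) / length(sd_pt),
              n_flagged = sum(flag),
              n_total = length(flag))
  if (per_pixel) out$per_pixel_sd <- apply(sd_pt, c(1, 2), sum)
  structure(out, class = "distortion_report")
}

#' @export
print.distortion_report <- function(x, ...) {
  cat(sprintf(
    "<distortion_report> SD total = %.6g (mean %.3g/point), %d of %d points flagged\n",
    x$sd_total, x$sd_mean, x$n_flagged, x$n_total))
  invisible(x)
}

#' SNR before and after denoising
#'
#' Companion summary to [signal_distortion()]: mean tissue SNR of the noisy
#' and the denoised cube.
#'
#' @param noisy,denoised [ftir_cube()] objects sharing shape and axis.
#' @param mask optional tissue mask (0 = tissue).
#' @param window band-free wavenumber interval.
#' @return Named numeric vector `c(snr_before, snr_after)`.
#' @export
snr_improvement <- function(noisy, denoised, mask = NULL,
                            window = DEFAULT_NOISE_WINDOW) {
  stopifnot_same_shape(noisy, denoised)
  c(snr_before = mean_snr(noisy, mask, window),
    snr_after = mean_snr(denoised, mask, window))
}
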