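make_triplet <- function(clean_v, noisy_v, den_v, ax = make_axis(816, 800, 4)) {
  wrap <- function(v, stage) ftir_cube(array(v, c(1, 1, length(ax))), ax, stage)
  list(clean = wrap(clean_v, "clean"), noisy = wrap(noisy_v, "noisy"),
       den = wrap(den_v, "denoised"))
}

test_that("signal distortion vanishes for perfect and for inert denoisers", {
  sc <- tiny_scene()
  noisy <- add_noise(sc$clean, noise_spec(0.01), seed = 60)
  # denoised == noisy: no residual change, nothing flagged
  r0 <- signal_distortion(sc$clean, noisy, noisy)
  expect_equal(r0$sd_total, 0)
  expect_equal(r0$n_flagged, 0)
  # denoised == clean: change equals original noise, strict inequality fails
  r1 <- signal_distortion(sc$clean, noisy, sc$clean)
  expect_equal(r1$sd_total, 0)
  expect_equal(r1$n_flagged, 0)
})

test_that("signal distortion flags overshoot past the original noise", {
  # clean 0, noisy 1, denoised -1: noise_abs 1, noise_absred 2, SD = 1
  tr <- make_triplet(0, 1, -1)
  rep_ <- signal_distortion(tr$clean, tr$noisy, tr$den)
  expect_equal(rep_$sd_total, length(tr$clean$axis) * 1)
  expect_equal(rep_$n_flagged, rep_$n_total)

  # single differing point
  cv <- rep(0, 5); nv <- rep(0, 5); dv <- rep(0, 5)
  nv[3] <- 1; dv[3] <- -1
  tr1 <- make_triplet(cv, nv, dv)
  expect_equal(signal_distortion(tr1$clean, tr1$noisy, tr1$den)$sd_total, 1)
  expect_equal(signal_distortion(tr1$clean, tr1$noisy, tr1$den)$n_flagged, 1)
})

test_that("signal distortion is scale-equivariant and overshoot-monotone", {
  sc <- tiny_scene()
  set.seed(61)
  noisy <- add_noise(sc$clean, noise_spec(0.008), seed = 61)
  den <- ftir_cube(sc$clean$data +
                     0.5 * (noisy$data - sc$clean$data) +
                     array(rnorm(length(noisy$data), 0, 0.004),
                           dim(noisy$data)),
                   sc$clean$axis, stage = "denoised")
  base <- signal_distortion(sc$clean, noisy, den)
  scale3 <- function(cb) ftir_cube(3 * cb$data, cb$axis, cb$meta$stage)
  scaled <- signal_distortion(scale3(sc$clean), scale3(noisy), scale3(den))
  expect_equal(scaled$sd_total, 3 * base$sd_total, tolerance = 1e-10)
  expect_equal(scaled$n_flagged, base$n_flagged)

  # pushing the denoised value further beyond never decreases the total
  worse <- ftir_cube(den$data + 0.5 * (den$data - noisy$data), den$axis,
                     "denoised")
  expect_gte(signal_distortion(sc$clean, noisy, worse)$sd_total, base$sd_total)
})

test_that("per-pixel distortion map sums to the total", {
  tr <- make_triplet(c(0, 0, 0, 0, 0), c(1, 0, 0, 0, 0), c(-1, 0, 0, 0, 0))
  rep_ <- signal_distortion(tr$clean, tr$noisy, tr$den, per_pixel = TRUE)
  expect_equal(sum(rep_$per_pixel_sd), rep_$sd_total)
  expect_error(signal_distortion(tr$clean, tr$noisy,
                                 ftir_cube(array(0, c(2, 2, 5)),
                                           make_axis(816, 800, 4))),
               "dimensions")
})

test_that("smoothing denoisers improve the measured SNR", {
  sc <- tiny_scene()
  noisy <- add_noise(sc$clean, noise_spec(0.01), seed = 62)
  smooth <- noisy$data
  for (k in seq_len(dim(smooth)[3]))
    smooth[, , k] <- ftirsim:::gauss_blur_plane(noisy$data[, , k], 1)
  den <- ftir_cube(smooth, noisy$axis, stage = "denoised")
  snr <- snr_improvement(noisy, den, sc$mask)
  expect_gt(snr[["snr_after"]], snr[["snr_before"]])
  # identical input: identical pair
  same <- snr_improvement(noisy, noisy, sc$mask)
  expect_equal(same[["snr_after"]], same[["snr_before"]])
  # the clean reference has far higher SNR than any noisy cube
  sep <- snr_improvement(noisy, sc$clean, sc$mask)
  expect_gt(sep[["snr_after"]], 10 * sep[["snr_before"]])
})
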