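test_that("wavenumber axis construction matches the instrument grid", {
  ax <- make_axis()
  expect_s3_class(ax, "spectral_axis")
  expect_length(ax, 765)
  expect_equal(ax[1], 3856)
  expect_equal(ax[765], 800)
  expect_true(all(diff(ax) == -4))

  expect_equal(as.numeric(make_axis(100, 96, 4)), c(100, 96))
  expect_length(make_axis(3850, 900, 4), 738)

  expect_error(make_axis(step = 0), "step")
  expect_error(make_axis(800, 3856), "exceed")
})

test_that("wavenumber/wavelength conversion is reciprocal centimetres", {
  expect_equal(wavenumber_to_wavelength(1650), 1e4 / 1650) # ~6.06 um
  expect_equal(wavenumber_to_wavelength(2000), 5)
  expect_equal(wavenumber_to_wavelength(800), 12.5)
  expect_error(wavenumber_to_wavelength(0), "positive")
  expect_error(wavenumber_to_wavelength(-5), "positive")
})

test_that("voigt_band matches brute-force Gaussian-Lorentzian convolution", {
  w <- voigt_widths(42)
  x <- seq(1250, 2050, by = 40)
  ref <- voigt_quadrature(x, 1650, w$sigma, w$gamma)
  expect_lt(max(abs(voigt_band(x, 1650, 42, 1) - ref) / ref), 1e-6)
  # far wings (asymptotic regime of the kernel)
  xw <- c(850, 3800)
  refw <- voigt_quadrature(xw, 1650, w$sigma, w$gamma)
  expect_lt(max(abs(voigt_band(xw, 1650, 42, 1) - refw) / refw), 1e-6)
})

test_that("voigt_band conserves area and total FWHM", {
  xa <- seq(-4000, 4000, by = 0.05) + 1650
  ya <- voigt_band(xa, 1650, 42, 1)
  expect_equal(sum((ya[-1] + ya[-length(ya)]) / 2) * 0.05, 1, tolerance = 0.01)

  xf <- seq(1550, 1750, by = 0.001)
  yf <- voigt_band(xf, 1650, 42, 1)
  half <- range(xf[yf >= max(yf) / 2])
  expect_equal(diff(half), 42, tolerance = 1e-3)
})

test_that("voigt_band edge behaviour: zero area, symmetry, Gaussian limit", {
  ax <- make_axis()
  expect_identical(voigt_band(ax, 1650, 42, 0), numeric(765))

  x <- seq(-60, 60, by = 0.5) + 1650
  y <- voigt_band(x, 1650, 30, 2)
  expect_equal(y, rev(y))

  # gamma -> 0 recovers a pure Gaussian of equal FWHM and area
  s <- 42 / (2 * sqrt(2 * log(2)))
  yg <- ftirsim:::.voigt_sum_cpp(x, 1650, s, 1e-10, 1)
  expect_equal(yg, dnorm(x, 1650, s), tolerance = 1e-8)

  expect_error(voigt_band(ax, 1650, -1, 1), "fwhm|positive")
  expect_error(voigt_band(ax, 1650, 42, -1), "area")
})

test_that("band table ships the sixteen tabulated bands", {
  tab <- default_band_table()
  expect_equal(nrow(tab), 16)
  expect_equal(tab$center_cm1,
               c(3300, 2962, 2920, 2850, 2352, 1754, 1650, 1550, 1462, 1400,
                 1342, 1280, 1242, 1172, 1080, 1030))
  expect_equal(tab$area_protein[tab$center_cm1 == 1650], 1.000)
  expect_equal(sum(is.na(tab$fwhm_sd_pct)), 1)
  expect_true(is.na(tab$fwhm_sd_pct[tab$center_cm1 == 2352]))
  expect_error(read_band_table(system.file("extdata", "band_table.csv",
                                           package = "ftirsim")), NA)
})

test_that("band randomization honours the tabulated standard deviations", {
  tab <- default_band_table()
  co2 <- tab[tab$center_cm1 == 2352, ]
  set.seed(1)
  draws <- replicate(500, randomize_band(co2, "protein"), simplify = FALSE)
  expect_true(all(vapply(draws, `[[`, numeric(1), "fwhm") == 27))
  expect_gt(sd(vapply(draws, `[[`, numeric(1), "center")), 0)

  # degenerate normals: zero SDs reproduce the nominal values
  flat <- co2
  flat$center_sd_pct <- 0
  out <- randomize_band(flat, "dna_rna", area_sd_pct = 0)
  expect_equal(out, list(center = 2352, fwhm = 27, area = 0.100))

  # stated SD of the 3300 band position: 1.8% of 3300
  b3300 <- tab[tab$center_cm1 == 3300, ]
  set.seed(2)
  centers <- replicate(2e4, randomize_band(b3300, "protein")$center)
  expect_equal(sd(centers), 0.018 * 3300, tolerance = 0.02)
})

test_that("class profiles reflect the tabulated band areas", {
  tab <- default_band_table()
  ax <- make_axis()
  prot <- generate_profile("protein", tab, ax, randomize = FALSE)
  lip <- generate_profile("lipid", tab, ax, randomize = FALSE)
  expect_true(all(prot >= 0) && all(is.finite(prot)))

  # amide I (area 1.000) is the tallest feature of the protein profile
  expect_equal(as.numeric(ax[which.max(prot)]), 1650, tolerance = 4)
  expect_equal(tab$area_protein[tab$center_cm1 == 1650], 1.000)

  # lipid CH-stretch bands exceed protein's
  ch <- tab$center_cm1 %in% c(2920, 2850)
  expect_true(all(tab$area_lipid[ch] > tab$area_protein[ch]))
  k29 <- which.min(abs(as.numeric(ax) - 2920))
  expect_gt(lip[k29], prot[k29])

  # determinism under a fixed seed
  set.seed(7)
  p1 <- generate_profile("dna_rna", tab, ax)
  set.seed(7)
  p2 <- generate_profile("dna_rna", tab, ax)
  expect_identical(p1, p2)

  # with randomization disabled the result is seed-independent
  set.seed(1)
  q1 <- generate_profile("lipid", tab, ax, randomize = FALSE)
  set.seed(99)
  q2 <- generate_profile("lipid", tab, ax, randomize = FALSE)
  expect_identical(q1, q2)

  expect_error(generate_profile("starch", tab, ax), "arg")
})

test_that("profile area units: per-point areas scale with the grid step", {
  tab <- default_band_table()
  ax <- make_axis()
  per_pt <- generate_profile("protein", tab, ax, randomize = FALSE)
  per_cm <- generate_profile("protein", tab, ax, randomize = FALSE,
                             area_units = "per_cm")
  expect_equal(as.numeric(per_pt), as.numeric(per_cm) * 4)
})
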