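# Shared fixtures, built once per test run and memoized.

memo <- local({
  cache <- new.env(parent = emptyenv())
  function(key, build) {
    if (!exists(key, cache)) assign(key, build(), cache)
    get(key, cache)
  }
})

# Small clean tissue cube (32 x 32, full default axis) with mask.
tiny_scene <- function() {
  memo("tiny", function() {
    maps <- synth_core_maps(32, 32, core_radius_px = 14, seed = 101)
    pre <- build_clean_cube(maps, seed = 102)
    clean <- blur_cube(pre)
    list(maps = maps, pre = pre, clean = clean, mask = build_mask(clean))
  })
}

# Desk cube (64 x 64) for SNR calibration and scan-series checks.
desk_scene <- function() {
  memo("desk", function() {
    maps <- synth_core_maps(64, 64, core_radius_px = 28, seed = 201)
    clean <- blur_cube(build_clean_cube(maps, seed = 202))
    list(maps = maps, clean = clean, mask = build_mask(clean))
  })
}

# Hand-built concentration maps (bypass the random phantom) for exact
# assembly checks.
manual_maps <- function(rows, cols, w_dna, w_protein, w_lipid,
                        core = matrix(TRUE, rows, cols)) {
  as_map <- function(w) matrix(w, rows, cols)
  structure(list(class_maps = list(dna_rna = as_map(w_dna),
                                   protein = as_map(w_protein),
                                   lipid = as_map(w_lipid)),
                 core = core, shape = c(rows, cols)),
            class = "conc_maps")
}

# Independent Voigt oracle: direct quadrature of the Gaussian (x) Lorentzian
# convolution, V(x) = int G(t; sigma) L(x - t; gamma) dt.
voigt_quadrature <- function(x, center, sigma, gamma) {
  vapply(x, function(xi) {
    stats::integrate(function(t) {
      stats::dnorm(t, 0, sigma) * (gamma / pi) / ((xi - center - t)^2 + gamma^2)
    }, -12 * sigma, 12 * sigma, rel.tol = 1e-12, abs.tol = 0)$value
  }, numeric(1))
}
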