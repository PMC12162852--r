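# fixtures shared across the suite; everything is generated in code

# a single Gaussian band on the default grid
gaussian_spectrum <- function(center = 1650, fwhm = 30, amplitude = 1,
                              grid = default_grid()) {
  component_band(band_shape(center, fwhm, "gaussian",
                            amplitude = amplitude), grid)
}

# spectrum from a plain absorbance vector on the default grid
vec_spectrum <- function(absorbance, grid = default_grid(), meta = list()) {
  ir_spectrum(grid, absorbance, meta = meta)
}

# small cohort configuration for pipeline-level tests
fast_config <- function(n_positive = 10, n_control = 10, seed = 101, ...) {
  cohort_config(n_positive = n_positive, n_control = n_control, seed = seed,
                ...)
}

# noiseless ratio of a two-conformer mixture after smoothing (the feature
# as the pipeline computes it)
mixture_ratio <- function(f_beta, grid = default_grid()) {
  s <- simulate_antigen_spectrum(conformer_fractions(1 - f_beta, 0, f_beta),
                                 grid)
  spectral_ratio(smooth_spectrum(s))
}

with_seed_compat <- function(seed, code) withr::with_seed(seed, code)

expect_spectra_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$wavenumbers, b$wavenumbers, tolerance = tol)
  expect_equal(a$absorbance, b$absorbance, tolerance = tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force Mann-Whitney oracle: enumerate all group assignments of the
# pooled sample and apply the same two-sided doubling rule as the exact
# rank-sum distribution
brute_mwu <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n2 <- length(y)
  u_stat <- function(xx, yy)
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  u_obs <- u_stat(x, y)
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  p <- if (u_obs > n1 * n2 / 2) 2 * mean(us >= u_obs)
       else 2 * mean(us <= u_obs)
  list(u_min = min(u_obs, n1 * n2 - u_obs), p = min(1, p))
}
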