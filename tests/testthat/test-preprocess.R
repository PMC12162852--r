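test_that("averaging is the pointwise mean with grid checking", {
  s <- gaussian_spectrum()
  avg <- average_spectra(list(s, s, s))
  expect_spectra_equal(avg, s)
  neg <- ir_spectrum(s$wavenumbers, -s$absorbance)
  expect_equal(average_spectra(list(s, neg))$absorbance,
               rep(0, length(s)))
  other <- gaussian_spectrum(grid = default_grid(by = 1))
  expect_error(average_spectra(list(s, other)), "spectrum 2")
  expect_error(average_spectra(list()), "no spectra")
})

test_that("averaging n noisy replicates shrinks the residual sd by sqrt(n)", {
  truth <- gaussian_spectrum(amplitude = 1e-3)
  sigma <- 1e-4
  reps <- with_seed_compat(42, lapply(1:100, function(i)
    ir_spectrum(truth$wavenumbers,
                truth$absorbance + stats::rnorm(length(truth), 0, sigma))))
  avg <- average_spectra(reps)
  resid_sd <- stats::sd(avg$absorbance - truth$absorbance)
  expect_lt(abs(resid_sd - sigma / 10), 0.2 * (sigma / 10))
})

test_that("difference spectra subtract exactly and check grids", {
  bg <- gaussian_spectrum(center = 1550, amplitude = 0.5)
  band <- gaussian_spectrum(center = 1650, amplitude = 1e-3)
  sample <- ir_spectrum(bg$wavenumbers, bg$absorbance + band$absorbance)
  expect_equal(difference_spectrum(sample, bg)$absorbance, band$absorbance)
  expect_equal(difference_spectrum(bg, bg)$absorbance, rep(0, length(bg)))
  expect_error(
    difference_spectrum(bg, gaussian_spectrum(grid = default_grid(by = 1))),
    "common wavenumber grid")
})

test_that("the vapor coefficient is recovered exactly in the noiseless case", {
  vref <- vapor_reference()
  clean <- gaussian_spectrum(center = 1550, fwhm = 50, amplitude = 1e-3)
  for (alpha in c(-1, 0, 0.01, 0.3, 2)) {
    s <- ir_spectrum(clean$wavenumbers,
                     clean$absorbance + alpha * vref$absorbance)
    corrected <- correct_water_vapor(s, vref)
    tr <- get_trace(corrected)
    fitted_alpha <- tr[[length(tr)]]$params$alpha
    expect_lt(abs(fitted_alpha - alpha), 1e-6)
    expect_lt(max(abs(corrected$absorbance - clean$absorbance)), 1e-6)
  }
})

test_that("vapor correction zeroes a pure-vapor spectrum and rejects a
           degenerate reference", {
  vref <- vapor_reference()
  corrected <- correct_water_vapor(vref, vref)
  idx <- spec_window(corrected, c(1700, 1900))
  expect_lt(max(abs(corrected$absorbance[idx])), 1e-12)
  zero_ref <- vec_spectrum(rep(0, length(default_grid())))
  expect_error(correct_water_vapor(vref, zero_ref), "degenerate")
})

test_that("two-anchor baseline removal is exact for lines and idempotent", {
  grid <- default_grid()
  ramp <- ir_spectrum(grid, 3e-6 * grid - 2e-3)
  expect_lt(max(abs(correct_baseline(ramp)$absorbance)), 1e-10)

  band <- gaussian_spectrum(center = 1650, fwhm = 20, amplitude = 1e-3)
  with_ramp <- ir_spectrum(grid, band$absorbance + 3e-6 * grid - 2e-3)
  expect_lt(max(abs(correct_baseline(with_ramp)$absorbance -
                    band$absorbance)), 1e-10)

  flat <- correct_baseline(band)
  expect_lt(max(abs(correct_baseline(flat)$absorbance - flat$absorbance)),
            1e-12)
  expect_error(correct_baseline(band, anchors = list(c(2000, 2010),
                                                     c(1480, 1490))),
               "empty")
})

test_that("Savitzky-Golay smoothing has the classical filter properties", {
  grid <- default_grid()
  # polynomial reproduction (degree <= polyorder) at interior points
  x <- (grid - 1690) / 100
  poly <- ir_spectrum(grid, 0.2 + 0.5 * x - 0.3 * x^2 + 0.1 * x^3)
  sm <- smooth_spectrum(poly, window = 9, polyorder = 3)
  interior <- 5:(length(grid) - 4)
  expect_lt(max(abs(sm$absorbance[interior] - poly$absorbance[interior])),
            1e-9)
  expect_true(isTRUE(sm$meta$smoothed))

  noise <- vec_spectrum(with_seed_compat(1, stats::rnorm(length(grid))))
  expect_lt(stats::var(smooth_spectrum(noise, 9, 3)$absorbance),
            stats::var(noise$absorbance))

  # impulse response: symmetric, support = window
  imp <- vec_spectrum(as.numeric(seq_along(grid) == 100))
  h <- smooth_spectrum(imp, 9, 3)$absorbance
  nz <- which(abs(h) > 1e-12)
  expect_equal(nz, 96:104)
  expect_equal(h[96:104], rev(h[96:104]), tolerance = 1e-12)

  expect_error(smooth_spectrum(noise, 8, 3), "odd")
  expect_error(smooth_spectrum(noise, 3, 3), "exceed")
  expect_error(smooth_spectrum(noise, 9999, 3), "grid")
})

test_that("Amide-I normalization scales to a unit maximum and is idempotent", {
  s <- gaussian_spectrum(amplitude = 2)
  n1 <- normalize_amide1(s)
  expect_equal(max(n1$absorbance[spec_window(n1, c(1600, 1700))]), 1)
  expect_equal(normalize_amide1(n1)$absorbance, n1$absorbance)
  # gain invariance
  s2 <- ir_spectrum(s$wavenumbers, 37.5 * s$absorbance)
  expect_equal(normalize_amide1(s2)$absorbance, n1$absorbance)
  flipped <- ir_spectrum(s$wavenumbers, -s$absorbance)
  expect_error(normalize_amide1(flipped), "nonpositive")
})

test_that("group differences vanish for identical groups and antisymmetrize", {
  a <- gaussian_spectrum(center = 1640, amplitude = 8e-4)
  b <- gaussian_spectrum(center = 1655, amplitude = 6e-4)
  expect_lt(max(abs(group_difference(list(a, b), list(a, b))$absorbance)),
            1e-12)
  d1 <- group_difference(list(a), list(b))
  d2 <- group_difference(list(b), list(a))
  expect_equal(d1$absorbance, -d2$absorbance, tolerance = 1e-12)
  expect_error(group_difference(list(), list(a)), "nonempty")
})

test_that("every stage appends to the processing trace in canonical order", {
  cc <- fast_config()
  run <- simulate_measurement_run(conformer_fractions(0.7, 0, 0.3), 5e-4,
                                  cc, seed = 4)
  proc <- process_run(run)
  stages <- vapply(get_trace(proc$difference), function(x) x$stage,
                   character(1))
  expect_equal(stages, c("average", "vapor_correction", "baseline",
                         "difference", "smooth"))
})

test_that("the processed read-outs are invariant under a positive gain", {
  cc <- fast_config(noise_sd = 0)
  run <- simulate_measurement_run(conformer_fractions(0.7, 0, 0.3), 5e-4,
                                  cc, seed = 13)
  scaled <- run
  for (part in c("background", "sample_wash"))
    scaled[[part]] <- lapply(run[[part]], function(s)
      ir_spectrum(s$wavenumbers, 3.7 * s$absorbance, meta = s$meta))
  p1 <- process_run(run)
  p2 <- process_run(scaled)
  expect_equal(spectral_ratio(p2$difference), spectral_ratio(p1$difference),
               tolerance = 1e-12)
  expect_equal(normalize_amide1(p2$difference)$absorbance,
               normalize_amide1(p1$difference)$absorbance, tolerance = 1e-9)
})
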