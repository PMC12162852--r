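test_that("component bands peak at their centers with the expected shapes", {
  g <- component_band(band_shape(1650, 40, "gaussian"))
  expect_equal(g$wavenumbers[which.max(g$absorbance)], 1650)

  l <- component_band(band_shape(1650, 40, "lorentzian"))
  # heavier tails: larger absorbance two FWHM away from the center
  expect_gt(spec_at(l, 1650 - 80), spec_at(g, 1650 - 80))
  expect_gt(spec_at(l, 1650 + 80), spec_at(g, 1650 + 80))

  pv0 <- component_band(band_shape(1650, 40, "pseudo_voigt", eta = 0))
  expect_equal(pv0$absorbance, g$absorbance, tolerance = 1e-12)

  narrow_grid <- seq(1660, 1640, by = -2)
  b <- component_band(band_shape(1650, 40, "gaussian"), narrow_grid)
  expect_true(isTRUE(b$meta$coverage_warning))
})

test_that("conformer fractions are validated", {
  expect_error(conformer_fractions(0.6, 0.6, 0.6), "sum to 1")
  expect_error(conformer_fractions(1.2, -0.2, 0), "\\[0, 1\\]")
  f <- conformer_fractions(0.25, 0.25)
  expect_equal(f$f_beta, 0.5)
})

test_that("single-conformer spectra peak at the conformer's band center", {
  for (grid_by in c(0.5, 1, 2)) {
    grid <- default_grid(by = grid_by)
    helix <- simulate_antigen_spectrum(conformer_fractions(1, 0, 0), grid)
    expect_lte(abs(absolute_max(helix) - 1650), grid_by / 2)
    beta <- simulate_antigen_spectrum(conformer_fractions(0, 0, 1), grid)
    expect_lte(abs(absolute_max(beta) - 1624), grid_by / 2)
    olig <- simulate_antigen_spectrum(conformer_fractions(0, 1, 0), grid)
    expect_lte(abs(absolute_max(olig) - 1647), grid_by / 2)
  }
})

test_that("a 50/50 mixture peaks strictly between the pure maxima", {
  mix <- simulate_antigen_spectrum(conformer_fractions(0.5, 0, 0.5))
  am <- absolute_max(mix)
  expect_gt(am, 1624)
  expect_lt(am, 1650)
})

test_that("the ratio decreases strictly as the beta fraction grows", {
  for (grid_by in c(0.5, 1, 2)) {
    grid <- default_grid(by = grid_by)
    ratios <- vapply(seq(0.05, 0.95, by = 0.1), mixture_ratio, numeric(1),
                     grid = grid)
    expect_true(all(diff(ratios) < 0))
  }
})

test_that("an amplitude-zero run carries no Amide-I signal", {
  cc <- fast_config()
  run <- simulate_measurement_run(conformer_fractions(0.7, 0, 0.3),
                                  amplitude = 0, config = cc, seed = 3)
  bg <- average_spectra(run$background)
  wash <- average_spectra(run$sample_wash)
  d <- difference_spectrum(wash, bg)
  idx <- spec_window(d, c(1600, 1700))
  expect_lte(abs(mean(d$absorbance[idx])), 3 * cc$noise_sd)
})

test_that("a noiseless run's processed difference recovers the mixture", {
  cc <- fast_config(noise_sd = 0)
  amp <- 1e-3
  fr <- conformer_fractions(0.65, 0, 0.35)
  run <- simulate_measurement_run(fr, amplitude = amp, config = cc, seed = 7)
  proc <- process_run(run)
  truth <- simulate_antigen_spectrum(fr, cc$grid)
  truth_scaled <- amp * truth$absorbance * truth$meta$amide1_area_ref /
    truth$meta$amide1_area
  # the chain baseline-corrects, so the oracle is the baseline-corrected
  # injected mixture
  truth_bc <- correct_baseline(ir_spectrum(cc$grid, truth_scaled))
  expect_lt(max(abs(proc$difference_raw$absorbance - truth_bc$absorbance)),
            0.01 * amp)
  idx <- spec_window(proc$difference_raw, c(1600, 1700))
  expect_gt(stats::cor(proc$difference_raw$absorbance[idx],
                       truth_scaled[idx]), 0.9999)
})

test_that("runs and cohorts are bitwise deterministic under a seed", {
  cc <- fast_config(n_positive = 3, n_control = 3, seed = 77)
  r1 <- simulate_measurement_run(conformer_fractions(0.7, 0, 0.3), 5e-4,
                                 cc, seed = 12)
  r2 <- simulate_measurement_run(conformer_fractions(0.7, 0, 0.3), 5e-4,
                                 cc, seed = 12)
  expect_identical(r1$sample_wash[[2]]$absorbance,
                   r2$sample_wash[[2]]$absorbance)
  expect_identical(r1$kinetics$absorbance, r2$kinetics$absorbance)

  s1 <- simulate_cohort(cc)
  s2 <- simulate_cohort(cc)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$runs[["C002"]]$background[[1]]$absorbance,
                   s2$runs[["C002"]]$background[[1]]$absorbance)
})

test_that("degenerate noiseless cohorts give identical within-group ratios", {
  bf <- list(positive = c(mu = stats::qlogis(0.4), sigma = 0),
             control = c(mu = stats::qlogis(0.2), sigma = 0))
  cc <- fast_config(n_positive = 3, n_control = 3, seed = 5,
                    beta_fraction = bf, noise_sd = 0, center_jitter_sd = 0)
  sim <- simulate_cohort(cc)
  ratios <- vapply(sim$records$subject_id, function(id) {
    spectral_ratio(process_run(sim$runs[[id]])$difference)
  }, numeric(1))
  g <- sim$records$group
  expect_lt(diff(range(ratios[g == "misfolding_positive"])), 1e-9)
  expect_lt(diff(range(ratios[g == "control"])), 1e-9)
  expect_lt(mean(ratios[g == "misfolding_positive"]),
            mean(ratios[g == "control"]))
})

test_that("control-only cohorts are valid and group sizes are enforced", {
  cc <- fast_config(n_positive = 0, n_control = 2, seed = 8)
  sim <- simulate_cohort(cc)
  expect_equal(nrow(sim$records), 2)
  expect_true(all(sim$records$group == "control"))
  expect_error(cohort_config(n_positive = 0, n_control = 0, seed = 1),
               "at least one subject")
  expect_error(cohort_config(n_positive = 5, n_control = 5), "seed")
})

test_that("calibrated cohort medians preserve the group ordering", {
  cc <- cohort_config(n_positive = 62, n_control = 72, seed = 20240425)
  sim <- simulate_cohort(cc)
  ratios <- vapply(sim$records$subject_id, function(id) {
    spectral_ratio(process_run(sim$runs[[id]])$difference)
  }, numeric(1))
  g <- sim$records$group
  expect_lt(stats::median(ratios[g == "misfolding_positive"]),
            stats::median(ratios[g == "control"]))
})

test_that("ThT scans reproduce the aggregation signatures", {
  agg <- simulate_tht_scans(TRUE, seed = 2)
  expect_equal(agg$excitation$wavelength[which.max(agg$excitation$intensity)],
               450)
  v <- tht_verdict(agg$excitation, agg$emission, agg$blank_emission)
  expect_true(v$aggregated)
  expect_gte(v$emission_factor, 20)

  mono <- simulate_tht_scans(FALSE, seed = 2)
  expect_equal(
    mono$excitation$wavelength[which.max(mono$excitation$intensity)], 413)
  v2 <- tht_verdict(mono$excitation, mono$emission, mono$blank_emission)
  expect_false(v2$aggregated)
  expect_lt(v2$emission_factor, 20)

  # blank against itself: factor 1 by definition
  v3 <- tht_verdict(mono$blank_excitation, mono$blank_emission,
                    mono$blank_emission)
  expect_equal(v3$emission_factor, 1)
})
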