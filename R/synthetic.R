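#' Conformer mixture fractions
#'
#' Fractions of the three alpha-synuclein conformer signals resolved on the
#' sensor: alpha-helical/random-coil (Amide-I maximum 1650 cm^-1),
#' dopamine-stabilized oligomer (1647 cm^-1) and beta-sheet fibril
#' (1624 cm^-1).
#'
#' @param f_helix_rc,f_oligomer,f_beta fractions in \[0, 1\] summing to 1
#' @return a `conformer_fractions` list
#' @export
conformer_fractions <- function(f_helix_rc, f_oligomer = 0,
                                f_beta = 1 - f_helix_rc - f_oligomer) {
  f <- c(f_helix_rc, f_oligomer, f_beta)
  if (any(f < -1e-12) || any(f > 1 + 1e-12))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(f) - 1) > 1e-9)
    stop("fractions must sum to 1 (got ", sum(f), ")", call. = FALSE)
  structure(list(f_helix_rc = f_helix_rc, f_oligomer = f_oligomer,
                 f_beta = f_beta), class = "conformer_fractions")
}

#' Simulate a captured-antigen absorbance spectrum
#'
#' Mixture of the three Amide-I component bands weighted by the conformer
#' fractions, plus an Amide-II band scaled to 0.75x the realized Amide-I
#' maximum, plus optional white noise. With `noise_sd = 0` and a single
#' nonzero fraction the Amide-I absolute maximum falls on the component's
#' center within half a grid step.
#'
#' @param fractions a [conformer_fractions()]
#' @param grid wavenumber grid
#' @param noise_sd additive Gaussian noise standard deviation (AU)
#' @param seed optional RNG seed (only used when `noise_sd > 0`)
#' @param bands band library, see [amide_band_library()]
#' @param center_shift rigid shift (cm^-1) applied to every band center;
#'   models subject-level variation of the difference-band positions
#' @return an [ir_spectrum()] with `meta$amide1_max` recording the noiseless
#'   Amide-I window maximum
#' @export
simulate_antigen_spectrum <- function(fractions, grid = default_grid(),
                                      noise_sd = 0, seed = NULL,
                                      bands = amide_band_library(),
                                      center_shift = 0) {
  stopifnot(inherits(fractions, "conformer_fractions"))
  shift <- function(b) { b$center <- b$center + center_shift; b }
  amide1 <- fractions$f_helix_rc * band_profile(shift(bands$helix_rc), grid) +
    fractions$f_oligomer * band_profile(shift(bands$oligomer), grid) +
    fractions$f_beta * band_profile(shift(bands$beta), grid)
  in_amide1 <- grid >= 1600 & grid <= 1700
  a1max <- max(amide1[in_amide1])
  amide2 <- bands$amide2$amplitude * a1max *
    band_profile(shift(band_shape(bands$amide2$center, bands$amide2$fwhm,
                                  bands$amide2$form, bands$amide2$eta, 1)),
                 grid)
  y <- amide1 + amide2
  if (noise_sd > 0)
    y <- y + with_local_seed(seed, stats::rnorm(length(grid), 0, noise_sd))
  trapz <- function(v) {
    x <- rev(grid[in_amide1]); yy <- rev(v[in_amide1])
    sum(diff(x) * (yy[-1] + yy[-length(yy)]) / 2)
  }
  ir_spectrum(grid, y,
              meta = list(amide1_max = a1max,
                          amide1_area = trapz(amide1),
                          amide1_area_ref =
                            trapz(band_profile(shift(bands$helix_rc), grid)),
                          fractions = unclass(fractions),
                          center_shift = center_shift))
}

#' Kinetics trace constructor
#' @param times seconds, strictly increasing
#' @param absorbance AU at the probe wavenumber
#' @param probe_wavenumber cm^-1 (1550 marks bound-protein Amide-II signal)
#' @return a `kinetics_trace`
#' @export
kinetics_trace <- function(times, absorbance, probe_wavenumber = 1550) {
  if (length(times) != length(absorbance))
    stop("times and absorbance differ in length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  structure(list(times = as.numeric(times),
                 absorbance = as.numeric(absorbance),
                 probe_wavenumber = probe_wavenumber),
            class = "kinetics_trace")
}

#' Cohort generator configuration
#'
#' Generative parameters for a synthetic study. Defaults reproduce the study
#' conditions: 62 misfolding-positive (PD/MSA) and 72 control subjects,
#' per-group beta-sheet-fraction distributions calibrated (logit-normal)
#' so that noiseless 1656.0/1623.5 ratio quartiles match the reported group
#' boxes (1.01-1.11 positives, 1.08-1.22 controls), physiological Amide-I
#' amplitudes around 5e-4 AU, and noise/drift/vapor levels at which default
#' runs pass both quality gates.
#'
#' @param n_positive,n_control group sizes (each >= 0, total >= 1)
#' @param seed mandatory integer seed; fans out to per-subject substreams by
#'   stable hashing of subject ids
#' @param beta_fraction per-group logit-normal parameters, a list
#'   `list(positive = c(mu, sigma), control = c(mu, sigma))`; `NULL` uses
#'   [calibrate_beta_fractions()]
#' @param noise_sd per-spectrum additive noise (AU)
#' @param baseline_drift range of baseline slopes (AU per cm^-1)
#' @param vapor_amplitude range of water-vapor line amplitudes (AU)
#' @param amplitude_meanlog,amplitude_sdlog log-normal parameters of the
#'   per-subject Amide-I amplitude (AU)
#' @param age per-group `c(mean, sd)` of age (years, truncated to 30-95)
#' @param female_fraction per-group probability of sex `F`
#' @param q_alb per-group `c(mean, sd)` of the CSF/serum albumin quotient
#' @param center_jitter_sd subject-level rigid band-center jitter (cm^-1)
#' @param n_replicates spectra per acquisition stage (background and wash)
#' @param grid wavenumber grid
#' @param kinetics list with `delay`, `tau`, `duration`, `step` (seconds)
#' @return a `cohort_config` list
#' @export
cohort_config <- function(n_positive = 62, n_control = 72, seed,
                          beta_fraction = NULL,
                          noise_sd = 1.5e-5,
                          baseline_drift = c(-2e-7, 2e-7),
                          vapor_amplitude = c(5e-5, 2e-4),
                          amplitude_meanlog = log(5e-4),
                          amplitude_sdlog = 0.25,
                          age = list(positive = c(mean = 70, sd = 8),
                                     control = c(mean = 70, sd = 9)),
                          female_fraction = c(positive = 0.23,
                                              control = 0.53),
                          q_alb = list(positive = c(mean = 10.1, sd = 5.5),
                                       control = c(mean = 7.3, sd = 3.5)),
                          center_jitter_sd = 1,
                          n_replicates = 10,
                          grid = default_grid(),
                          kinetics = list(delay = 600, tau = 1200,
                                          duration = 7200, step = 60)) {
  if (missing(seed) || is.null(seed))
    stop("cohort_config requires an explicit seed", call. = FALSE)
  if (n_positive < 0 || n_control < 0 || n_positive + n_control < 1)
    stop("cohort must contain at least one subject", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(beta_fraction))
    beta_fraction <- calibrate_beta_fractions(
      grid = grid, center_jitter_sd = center_jitter_sd)
  structure(list(n_positive = n_positive, n_control = n_control,
                 seed = as.integer(seed), beta_fraction = beta_fraction,
                 noise_sd = noise_sd, baseline_drift = baseline_drift,
                 vapor_amplitude = vapor_amplitude,
                 amplitude_meanlog = amplitude_meanlog,
                 amplitude_sdlog = amplitude_sdlog,
                 age = age, female_fraction = female_fraction,
                 q_alb = q_alb, center_jitter_sd = center_jitter_sd,
                 n_replicates = n_replicates, grid = grid,
                 kinetics = kinetics),
            class = "cohort_config")
}

.calibration_cache <- new.env(parent = emptyenv())

#' Calibrate per-group beta-fraction distributions
#'
#' Inverts the noiseless forward model (mixture spectrum -> 1656.0/1623.5
#' ratio, a strictly decreasing function of the beta fraction) at the
#' reported group interquartile bounds. The logit-normal location is set at
#' the beta fraction reproducing the box midpoint; the scale is chosen so
#' the total ratio variance — the beta-fraction contribution plus the
#' variance induced by the subject-level band-center jitter — matches the
#' box-implied interquartile spread.
#'
#' @param box_positive,box_control reported interquartile bounds of the
#'   ratio per group
#' @param grid wavenumber grid used for the inversion
#' @param center_jitter_sd subject-level band-center jitter (cm^-1) whose
#'   ratio variance is budgeted against the box spread
#' @return list with per-group `c(mu, sigma)` on the logit scale
#' @export
calibrate_beta_fractions <- function(box_positive = c(1.01, 1.11),
                                     box_control = c(1.08, 1.22),
                                     grid = default_grid(),
                                     center_jitter_sd = 1) {
  key <- paste(c(box_positive, box_control, range(grid), length(grid),
                 center_jitter_sd), collapse = "|")
  if (!is.null(.calibration_cache[[key]])) return(.calibration_cache[[key]])
  ratio_of <- function(f, shift = 0) {
    s <- simulate_antigen_spectrum(conformer_fractions(1 - f, 0, f), grid,
                                   center_shift = shift)
    # the read-out is defined on smoothed difference spectra, so the
    # inversion must see the same operator
    spectral_ratio(smooth_spectrum(s))
  }
  inv <- function(r)
    stats::uniroot(function(f) ratio_of(f) - r, c(0.005, 0.995),
                   tol = 1e-8)$root
  params <- function(box) {
    f_med <- inv(mean(box))
    target_sd <- (box[2] - box[1]) / (2 * stats::qnorm(0.75))
    dr_dshift <- (ratio_of(f_med, 1) - ratio_of(f_med, -1)) / 2
    sd_jitter <- abs(dr_dshift) * center_jitter_sd
    sd_f <- sqrt(max(target_sd^2 - sd_jitter^2, (0.25 * target_sd)^2))
    h <- 0.01
    dr_df <- (ratio_of(f_med + h) - ratio_of(f_med - h)) / (2 * h)
    sigma <- sd_f / abs(dr_df) / (f_med * (1 - f_med))
    c(mu = stats::qlogis(f_med), sigma = sigma)
  }
  out <- list(positive = params(box_positive), control = params(box_control))
  .calibration_cache[[key]] <- out
  out
}

#' Simulate one subject's acquisition
#'
#' Forward model for a sensor run: replicate background spectra (baseline
#' drift + water-vapor lines + noise), replicate sample-wash spectra
#' (background components + the scaled conformer mixture), and a saturating
#' exponential binding kinetics trace at the probe wavenumber. An amplitude
#' of 0 reproduces the null signal of a re-measured (antigen-depleted)
#' sample.
#'
#' @param fractions a [conformer_fractions()]
#' @param amplitude Amide-I peak absorbance (AU, >= 0) that an all-helical
#'   capture of the same protein mass would show; physiological scale
#'   ~1e-4 to 1e-3. Mixtures are scaled to a common integrated Amide-I area
#'   (mass conservation), so the realized peak varies with composition
#' @param config a [cohort_config()] providing noise/drift/vapor/grid
#'   parameters
#' @param seed integer seed for this run
#' @param subject_id subject identifier stored on the run
#' @param center_shift rigid band-center shift (cm^-1) for this subject
#' @return a `measurement_run` list (`background`, `sample_wash`,
#'   `kinetics`, `subject_id`, `channel`, `reference_channel`)
#' @export
simulate_measurement_run <- function(fractions, amplitude, config, seed,
                                     subject_id = "S1", center_shift = 0) {
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  grid <- config$grid
  mix <- simulate_antigen_spectrum(fractions, grid, noise_sd = 0,
                                   center_shift = center_shift)
  # mass conservation: the same amount of captured protein redistributes
  # between conformers, so mixtures are scaled to a common integrated
  # Amide-I area; `amplitude` is the Amide-I peak absorbance an all-helical
  # capture of that mass would show
  unit_mix <- mix$absorbance * mix$meta$amide1_area_ref /
    mix$meta$amide1_area
  vref <- vapor_reference(grid)$absorbance
  with_local_seed(seed, {
    # the baseline is a run-level property (the optical background drifts
    # only slightly between acquisition stages), whereas the atmospheric
    # vapor level is drawn per stage, leaving a sharp-line residual in the
    # raw difference that only the vapor-correction stage removes
    bd <- config$baseline_drift
    slope0 <- stats::runif(1, bd[1], bd[2])
    offset0 <- stats::runif(1, -5e-5, 5e-5)
    stage <- function(signal_au, n) {
      slope <- slope0 + stats::runif(1, -0.05, 0.05) * (bd[2] - bd[1])
      offset <- offset0 + stats::runif(1, -2e-6, 2e-6)
      vamp <- stats::runif(1, config$vapor_amplitude[1],
                           config$vapor_amplitude[2])
      base <- offset + slope * (grid - 1700) + vamp * vref +
        signal_au * unit_mix
      lapply(seq_len(n), function(i) {
        noise <- if (config$noise_sd > 0)
          stats::rnorm(length(grid), 0, config$noise_sd) else 0
        ir_spectrum(grid, base + noise,
                    meta = list(subject_id = subject_id, replicate = i,
                                smoothed = FALSE))
      })
    }
    background <- stage(0, config$n_replicates)
    wash <- stage(amplitude, config$n_replicates)
    kp <- config$kinetics
    times <- seq(0, kp$duration, by = kp$step)
    plateau <- amplitude * stats::approx(rev(grid), rev(unit_mix),
                                         xout = 1550)$y
    a <- ifelse(times <= kp$delay, 0,
                plateau * (1 - exp(-(times - kp$delay) / kp$tau)))
    if (config$noise_sd > 0)
      a <- a + stats::rnorm(length(times), 0, config$noise_sd)
    structure(list(background = background, sample_wash = wash,
                   kinetics = kinetics_trace(times, a),
                   subject_id = subject_id, channel = "ch1",
                   reference_channel = FALSE),
              class = "measurement_run")
  })
}

# deterministic diagnosis assignment reproducing the combined cohort makeup
# (57 PD + 5 MSA positives; 51 disease controls + 5 CBD + 7 FTD + 9 PSP)
.assign_diagnoses <- function(n, group) {
  if (n == 0) return(character(0))
  if (group == "positive") {
    n_msa <- round(n * 5 / 62)
    c(rep("PD", n - n_msa), rep("MSA", n_msa))
  } else {
    k <- round(n * c(CBD = 5, FTD = 7, PSP = 9) / 72)
    c(rep("control", n - sum(k)), rep("CBD", k["CBD"]),
      rep("FTD", k["FTD"]), rep("PSP", k["PSP"]))
  }
}

#' Simulate a full cohort
#'
#' Draws per-subject beta fractions from the group's calibrated logit-normal
#' distribution, demographics (age, sex, albumin quotient) from per-group
#' parameters, and one measurement run per subject. All randomness derives
#' from per-subject substreams of `config$seed`, so the output is bitwise
#' reproducible and independent of iteration order.
#'
#' @param config a [cohort_config()]
#' @return list with `records` (data.frame: subject_id, diagnosis, group,
#'   age, sex, q_alb, plus the generative `f_beta` and `amplitude`) and
#'   `runs` (named list of `measurement_run`s)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- c(rep("positive", config$n_positive),
              rep("control", config$n_control))
  ids <- c(sprintf("P%03d", seq_len(config$n_positive)),
           sprintf("C%03d", seq_len(config$n_control)))
  diagnosis <- c(.assign_diagnoses(config$n_positive, "positive"),
                 .assign_diagnoses(config$n_control, "control"))
  n <- length(ids)
  rec <- vector("list", n)
  runs <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    bf <- config$beta_fraction[[g]]
    ss <- substream_seed(config$seed, ids[i])
    draws <- with_local_seed(ss, {
      f_beta <- stats::plogis(stats::rnorm(1, bf[["mu"]], bf[["sigma"]]))
      ap <- config$age[[g]]
      age <- min(max(stats::rnorm(1, ap[["mean"]], ap[["sd"]]), 30), 95)
      sex <- if (stats::runif(1) < config$female_fraction[[g]]) "F" else "M"
      qp <- config$q_alb[[g]]
      shape <- (qp[["mean"]] / qp[["sd"]])^2
      q_alb <- stats::rgamma(1, shape = shape,
                             scale = qp[["sd"]]^2 / qp[["mean"]])
      amplitude <- stats::rlnorm(1, config$amplitude_meanlog,
                                 config$amplitude_sdlog)
      shift <- stats::rnorm(1, 0, config$center_jitter_sd)
      list(f_beta = f_beta, age = age, sex = sex, q_alb = q_alb,
           amplitude = amplitude, shift = shift)
    })
    runs[[i]] <- simulate_measurement_run(
      conformer_fractions(1 - draws$f_beta, 0, draws$f_beta),
      amplitude = draws$amplitude, config = config,
      seed = substream_seed(config$seed, paste0(ids[i], "/run")),
      subject_id = ids[i], center_shift = draws$shift)
    rec[[i]] <- data.frame(subject_id = ids[i], diagnosis = diagnosis[i],
                           age = draws$age, sex = draws$sex,
                           q_alb = draws$q_alb, f_beta = draws$f_beta,
                           amplitude = draws$amplitude,
                           stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec)
  records$group <- derive_group(records$diagnosis)
  names(runs) <- ids
  list(records = records[c("subject_id", "diagnosis", "group", "age", "sex",
                           "q_alb", "f_beta", "amplitude")],
       runs = runs)
}

#' Simulate thioflavin T verification scans
#'
#' Fixtures for the aggregation check: beta-sheet-rich material shifts the
#' ThT excitation maximum from 413 nm (free dye) to 450 nm (intercalated
#' dye) and raises the 482 nm emission at least 20-fold over the blank;
#' monomeric material keeps the 413 nm maximum and a small emission factor.
#'
#' @param is_aggregated logical; simulate aggregated (fibrillar) material?
#' @param seed RNG seed
#' @return list of data.frames (`wavelength`, `intensity`): `excitation`
#'   (410-460 nm), `emission` (480-620 nm), `blank_excitation`,
#'   `blank_emission`
#' @export
simulate_tht_scans <- function(is_aggregated, seed = 1) {
  ex_wl <- 410:460
  em_wl <- 480:620
  with_local_seed(seed, {
    blank_ex <- 2 + abs(stats::rnorm(length(ex_wl), 0, 0.02))
    blank_em <- 100 + stats::rnorm(length(em_wl), 0, 0.5)
    if (is_aggregated) {
      ex <- blank_ex + 1000 * band_profile(band_shape(450, 30, "gaussian"),
                                           ex_wl)
      em <- blank_em + 3000 * band_profile(band_shape(483, 50, "gaussian"),
                                           em_wl)
    } else {
      ex <- blank_ex + 300 * band_profile(band_shape(413, 25, "gaussian"),
                                          ex_wl)
      em <- blank_em + 200 * band_profile(band_shape(483, 50, "gaussian"),
                                          em_wl)
    }
    list(excitation = data.frame(wavelength = ex_wl, intensity = ex),
         emission = data.frame(wavelength = em_wl, intensity = em),
         blank_excitation = data.frame(wavelength = ex_wl,
                                       intensity = blank_ex),
         blank_emission = data.frame(wavelength = em_wl,
                                     intensity = blank_em))
  })
}
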