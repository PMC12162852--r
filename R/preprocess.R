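#' Average replicate spectra
#'
#' Pointwise arithmetic mean of replicate spectra sharing one grid; the
#' first stage of the canonical processing chain
#' average -> vapor-correct -> baseline-correct -> difference -> smooth.
#'
#' @param spectra nonempty list of `ir_spectrum`s on a common grid
#' @return an [ir_spectrum()]; `n` averaged recorded in the trace
#' @export
average_spectra <- function(spectra) {
  if (!length(spectra)) stop("no spectra to average", call. = FALSE)
  ref <- spectra[[1]]
  for (i in seq_along(spectra)) {
    if (!same_grid(ref, spectra[[i]]))
      stop("spectrum ", i, " is not on the common wavenumber grid",
           call. = FALSE)
  }
  m <- rowMeans(vapply(spectra, function(s) s$absorbance,
                       numeric(length(ref))))
  out <- ir_spectrum(ref$wavenumbers, m, meta = ref$meta)
  out$meta$smoothed <- FALSE
  add_trace(out, "average", list(n = length(spectra)))
}

#' Sample-minus-background difference spectrum
#'
#' @param sample,background `ir_spectrum`s on a common grid
#' @return `sample - background` as an [ir_spectrum()]; the traces of both
#'   inputs are concatenated
#' @export
difference_spectrum <- function(sample, background) {
  stop_if_grid_mismatch(sample, background)
  out <- ir_spectrum(sample$wavenumbers,
                     sample$absorbance - background$absorbance,
                     meta = sample$meta)
  out$meta$smoothed <- FALSE
  add_trace(out, "difference",
            list(background_trace = get_trace(background)))
}

#' Subtract scaled water-vapor reference
#'
#' Fits the vapor coefficient by least squares on second differences over
#' the protein-free diagnostic window (1900-1700 cm^-1 by default): sharp
#' rotational lines dominate the curvature there while broad protein and
#' baseline contributions are nearly line-free, so for a spectrum
#' `clean + alpha * vapor_ref` the coefficient is recovered exactly in the
#' noiseless case.
#'
#' @param s an `ir_spectrum`
#' @param vapor_ref vapor reference spectrum on the same grid (see
#'   [vapor_reference()])
#' @param window diagnostic window (cm^-1)
#' @return corrected spectrum; the fitted coefficient `alpha` is recorded in
#'   the trace
#' @export
correct_water_vapor <- function(s, vapor_ref, window = c(1700, 1900)) {
  stop_if_grid_mismatch(s, vapor_ref, "spectrum and vapor reference")
  if (all(vapor_ref$absorbance == 0))
    stop("degenerate vapor reference (all zeros)", call. = FALSE)
  idx <- spec_window(s, window)
  if (length(idx) < 4L)
    stop("vapor diagnostic window too short on this grid", call. = FALSE)
  d2s <- diff(s$absorbance[idx], differences = 2)
  d2v <- diff(vapor_ref$absorbance[idx], differences = 2)
  denom <- sum(d2v^2)
  if (denom == 0)
    stop("vapor reference has no curvature in the diagnostic window",
         call. = FALSE)
  alpha <- sum(d2s * d2v) / denom
  out <- ir_spectrum(s$wavenumbers, s$absorbance - alpha * vapor_ref$absorbance,
                     meta = s$meta)
  add_trace(out, "vapor_correction", list(alpha = alpha, window = window))
}

#' Two-anchor linear baseline correction
#'
#' Subtracts the straight line through the mean absorbance of two anchor
#' windows chosen in protein-free regions flanking the Amide bands.
#'
#' @param s an `ir_spectrum`
#' @param anchors list of two numeric windows (cm^-1)
#' @return baseline-corrected spectrum; anchor means recorded in the trace
#' @export
correct_baseline <- function(s, anchors = list(c(1750, 1800), c(1480, 1490))) {
  if (length(anchors) != 2L)
    stop("exactly two anchor windows are required", call. = FALSE)
  pts <- lapply(anchors, function(w) {
    idx <- tryCatch(spec_window(s, w), error = function(e)
      stop("baseline anchor window [", min(w), ", ", max(w),
           "] is empty on this grid", call. = FALSE))
    c(x = mean(s$wavenumbers[idx]), y = mean(s$absorbance[idx]))
  })
  x1 <- pts[[1]]["x"]; y1 <- pts[[1]]["y"]
  x2 <- pts[[2]]["x"]; y2 <- pts[[2]]["y"]
  slope <- (y2 - y1) / (x2 - x1)
  line <- y1 + slope * (s$wavenumbers - x1)
  out <- ir_spectrum(s$wavenumbers, s$absorbance - line, meta = s$meta)
  add_trace(out, "baseline", list(anchors = anchors,
                                  anchor_means = c(y1, y2), slope = slope))
}

#' Savitzky-Golay smoothing
#'
#' Local polynomial smoothing of the difference spectrum. The smoothed flag
#' is set in `meta`; signal-to-noise must always be computed on the
#' unsmoothed spectrum, so retain the input.
#'
#' @param s an `ir_spectrum`
#' @param window odd filter length in points (> `polyorder`)
#' @param polyorder polynomial order
#' @return smoothed spectrum with `meta$smoothed = TRUE`
#' @export
smooth_spectrum <- function(s, window = 9, polyorder = 3) {
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (window <= polyorder)
    stop("window must exceed the polynomial order", call. = FALSE)
  if (window > length(s$wavenumbers))
    stop("window exceeds the number of grid points", call. = FALSE)
  y <- signal::sgolayfilt(s$absorbance, p = polyorder, n = window)
  out <- ir_spectrum(s$wavenumbers, y, meta = s$meta)
  out$meta$smoothed <- TRUE
  add_trace(out, "smooth", list(window = window, polyorder = polyorder))
}

#' Normalize to unit Amide-I maximum
#'
#' Scales a spectrum so its Amide-I window (1700-1600 cm^-1) maximum equals
#' 1. A nonpositive maximum signals a failed run and raises an error.
#'
#' @param s an `ir_spectrum`
#' @param window Amide-I window (cm^-1)
#' @return normalized spectrum; the scale factor is recorded in the trace
#' @export
normalize_amide1 <- function(s, window = c(1600, 1700)) {
  idx <- spec_window(s, window)
  m <- max(s$absorbance[idx])
  if (m <= 0)
    stop("nonpositive Amide-I maximum: cannot normalize (failed run?)",
         call. = FALSE)
  out <- ir_spectrum(s$wavenumbers, s$absorbance / m, meta = s$meta)
  add_trace(out, "normalize_amide1", list(scale = 1 / m))
}

#' Group difference spectrum
#'
#' Mean of per-spectrum Amide-I-normalized positives minus mean of
#' normalized controls, followed by baseline correction. With
#' `normalize = "difference"` the raw group means are differenced first and
#' the result normalized to its Amide-I absolute maximum instead.
#'
#' @param positives,controls nonempty lists of `ir_spectrum`s (processed
#'   per-subject difference spectra) on one grid
#' @param normalize `"per_spectrum"` (default) or `"difference"`
#' @param anchors baseline anchor windows, see [correct_baseline()]
#' @return the group difference as an [ir_spectrum()]
#' @export
group_difference <- function(positives, controls,
                             normalize = c("per_spectrum", "difference"),
                             anchors = list(c(1750, 1800), c(1480, 1490))) {
  normalize <- match.arg(normalize)
  if (!length(positives) || !length(controls))
    stop("both groups must be nonempty", call. = FALSE)
  if (normalize == "per_spectrum") {
    pos <- average_spectra(lapply(positives, normalize_amide1))
    ctl <- average_spectra(lapply(controls, normalize_amide1))
    d <- difference_spectrum(pos, ctl)
  } else {
    pos <- average_spectra(positives)
    ctl <- average_spectra(controls)
    d <- difference_spectrum(pos, ctl)
    idx <- spec_window(d, c(1600, 1700))
    m <- max(abs(d$absorbance[idx]))
    if (m <= 0) stop("zero group difference: cannot normalize", call. = FALSE)
    d <- ir_spectrum(d$wavenumbers, d$absorbance / m, meta = d$meta)
  }
  out <- correct_baseline(d, anchors = anchors)
  add_trace(out, "group_difference",
            list(n_positive = length(positives),
                 n_control = length(controls), normalize = normalize))
}

#' Process one measurement run
#'
#' Applies the canonical chain to a run: average the background and wash
#' replicates, vapor-correct and baseline-correct each average, take the
#' wash-minus-background difference, and smooth. The unsmoothed difference
#' is retained for signal-to-noise computation.
#'
#' @param run a `measurement_run`
#' @param vapor_ref vapor reference spectrum on the run's grid
#' @param smooth_window,smooth_polyorder Savitzky-Golay parameters
#' @param anchors baseline anchor windows
#' @return list with `difference` (smoothed), `difference_raw` (unsmoothed),
#'   `background_avg`, `wash_avg`
#' @export
process_run <- function(run, vapor_ref = NULL, smooth_window = 9,
                        smooth_polyorder = 3,
                        anchors = list(c(1750, 1800), c(1480, 1490))) {
  stopifnot(inherits(run, "measurement_run"))
  if (!length(run$background) || !length(run$sample_wash))
    stop("run must contain background and sample-wash spectra",
         call. = FALSE)
  if (is.null(vapor_ref))
    vapor_ref <- vapor_reference(run$background[[1]]$wavenumbers)
  chain <- function(spectra) {
    s <- average_spectra(spectra)
    s <- correct_water_vapor(s, vapor_ref)
    correct_baseline(s, anchors = anchors)
  }
  bg <- chain(run$background)
  wash <- chain(run$sample_wash)
  raw <- difference_spectrum(wash, bg)
  raw$meta$subject_id <- run$subject_id
  sm <- smooth_spectrum(raw, window = smooth_window,
                        polyorder = smooth_polyorder)
  list(difference = sm, difference_raw = raw, background_avg = bg,
       wash_avg = wash)
}
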