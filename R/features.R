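#' Absolute Amide-I peak maximum position
#'
#' Wavenumber of the maximum absorbance inside the window; ties are broken
#' toward the higher wavenumber.
#'
#' @param s an `ir_spectrum`
#' @param window search window (cm^-1)
#' @return wavenumber (cm^-1)
#' @export
absolute_max <- function(s, window = c(1600, 1700)) {
  idx <- spec_window(s, window)
  a <- s$absorbance[idx]
  w <- s$wavenumbers[idx]
  cand <- w[a == max(a)]
  max(cand)
}

#' Center-of-mass maximum of a band
#'
#' Intensity-weighted mean wavenumber over the points whose absorbance
#' reaches at least `fraction` of the window maximum (the upper 80-90% of
#' the band). More robust than the absolute maximum for small signals.
#'
#' @param s an `ir_spectrum`
#' @param window search window (cm^-1)
#' @param fraction threshold fraction of the window maximum, in
#'   \[0.80, 0.90\] by convention (default 0.85)
#' @return wavenumber (cm^-1)
#' @export
com_max <- function(s, window = c(1600, 1700), fraction = 0.85) {
  idx <- spec_window(s, window)
  a <- s$absorbance[idx]
  w <- s$wavenumbers[idx]
  amax <- max(a)
  if (amax <= 0)
    stop("nonpositive maximum in window: no band to locate", call. = FALSE)
  keep <- a >= fraction * amax
  sum(w[keep] * a[keep]) / sum(a[keep])
}

#' Spectral absorbance ratio at two wavenumbers
#'
#' The primary misfolding read-out: the ratio of the absorbance at the
#' alpha-helical/random-coil difference-band position (1656.0 cm^-1) to the
#' beta-sheet position (1623.5 cm^-1), evaluated by linear interpolation on
#' the processed (smoothed) per-subject difference spectrum. The ratio
#' decreases as the beta-sheet content grows.
#'
#' @param s an `ir_spectrum`
#' @param nu_num,nu_den numerator and denominator wavenumbers (cm^-1)
#' @return dimensionless ratio, or `NA` (with a warning) when the
#'   denominator absorbance is nonpositive; callers must flag rather than
#'   silently drop such subjects
#' @export
spectral_ratio <- function(s, nu_num = 1656.0, nu_den = 1623.5) {
  num <- spec_at(s, nu_num)
  den <- spec_at(s, nu_den)
  if (den <= 0) {
    warning("nonpositive absorbance at ", nu_den,
            " cm-1: ratio marked invalid")
    return(NA_real_)
  }
  num / den
}

#' Integrals of the positive and negative lobes of a group difference
#'
#' Trapezoidal integrals of a normalized, baseline-corrected group
#' difference spectrum over the beta-sheet (positive) and
#' helix/random-coil (negative) lobes. By default the boundary between the
#' windows is moved to the zero crossing nearest 1640 cm^-1 when one exists
#' inside 1630-1650 cm^-1. Each lobe is integrated with its sign and
#' reported as a magnitude.
#'
#' @param diff group difference spectrum (see [group_difference()])
#' @param pos_window,neg_window integration windows (cm^-1); they may share
#'   at most their common boundary
#' @param boundary `"zero_crossing"` (default) or `"fixed"`
#' @return list with `positive_integral`, `negative_integral` (both >= 0,
#'   AU cm^-1) and the `windows` used
#' @export
band_integrals <- function(diff, pos_window = c(1608, 1640),
                           neg_window = c(1640, 1672),
                           boundary = c("zero_crossing", "fixed")) {
  boundary <- match.arg(boundary)
  if (max(pos_window) > min(neg_window))
    stop("integration windows overlap beyond a shared boundary",
         call. = FALSE)
  if (boundary == "zero_crossing" &&
      isTRUE(all.equal(max(pos_window), min(neg_window)))) {
    b <- max(pos_window)
    xc <- .zero_crossing_near(diff, b, span = c(1630, 1650))
    if (!is.na(xc)) {
      pos_window <- c(min(pos_window), xc)
      neg_window <- c(xc, max(neg_window))
    }
  }
  pos <- abs(.window_integral(diff, pos_window))
  neg <- abs(.window_integral(diff, neg_window))
  list(positive_integral = pos, negative_integral = neg,
       windows = list(positive = pos_window, negative = neg_window))
}

# trapezoidal integral over a closed window with linearly interpolated
# endpoint values
.window_integral <- function(s, window) {
  lo <- min(window); hi <- max(window)
  x <- rev(s$wavenumbers)  # ascending
  y <- rev(s$absorbance)
  inside <- x > lo & x < hi
  xs <- c(lo, x[inside], hi)
  ys <- c(stats::approx(x, y, xout = lo)$y, y[inside],
          stats::approx(x, y, xout = hi)$y)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

.zero_crossing_near <- function(s, target, span = c(1630, 1650)) {
  x <- rev(s$wavenumbers)
  y <- rev(s$absorbance)
  keep <- x >= span[1] & x <= span[2]
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) return(NA_real_)
  sgn <- sign(y)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(flips)) return(NA_real_)
  xc <- vapply(flips, function(i) {
    x[i] - y[i] * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
  }, numeric(1))
  xc[which.min(abs(xc - target))]
}

#' Plateau amplitude of a binding kinetics trace
#'
#' Mean of the final 10% of the trace minus the mean of the first 5%
#' (pre-binding baseline). Invariant to a constant offset.
#'
#' @param k a [kinetics_trace()] with at least 10 points
#' @return amplitude (AU)
#' @export
kinetic_amplitude <- function(k) {
  stopifnot(inherits(k, "kinetics_trace"))
  n <- length(k$times)
  if (n < 10L) stop("kinetics trace too short (need >= 10 points)",
                    call. = FALSE)
  t0 <- k$times[1]
  t1 <- k$times[n]
  span <- t1 - t0
  head_idx <- which(k$times <= t0 + 0.05 * span)
  tail_idx <- which(k$times >= t1 - 0.10 * span)
  mean(k$absorbance[tail_idx]) - mean(k$absorbance[head_idx])
}

#' Extract the per-subject feature set from a processed run
#'
#' @param processed output of [process_run()]
#' @param qc optional [run_qc()] report to attach; computed from the
#'   processed spectra when omitted
#' @param kinetics optional [kinetics_trace()] for the kinetic amplitude
#' @param com_fraction threshold fraction for [com_max()]
#' @return a `feature_set` list: `abs_max`, `com_max`, `ratio_1656_1623`,
#'   `kinetic_amplitude`, `qc`
#' @export
extract_features <- function(processed, qc = NULL, kinetics = NULL,
                             com_fraction = 0.85) {
  s <- processed$difference
  if (is.null(qc)) qc <- run_qc(s, processed$difference_raw)
  ratio <- suppressWarnings(spectral_ratio(s))
  structure(list(
    abs_max = absolute_max(s),
    com_max = com_max(s, fraction = com_fraction),
    ratio_1656_1623 = ratio,
    kinetic_amplitude = if (!is.null(kinetics)) kinetic_amplitude(kinetics)
                        else NA_real_,
    qc = qc), class = "feature_set")
}
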