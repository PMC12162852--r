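#' Amide-I/Amide-II peak ratio
#'
#' Quality indicator of an unnormalized difference spectrum: the maximum
#' absorbance in the Amide-I window divided by the maximum in the Amide-II
#' window. Distorted spectra (water background drift, temperature
#' instability) leave the acceptance range 1.10-1.50.
#'
#' @param s an `ir_spectrum` (unnormalized difference spectrum)
#' @param amide1_window,amide2_window windows in cm^-1
#' @return dimensionless ratio
#' @export
amide_ratio <- function(s, amide1_window = c(1600, 1700),
                        amide2_window = c(1500, 1580)) {
  a1 <- max(s$absorbance[spec_window(s, amide1_window)])
  a2 <- max(s$absorbance[spec_window(s, amide2_window)])
  if (a2 <= 0)
    stop("nonpositive Amide-II maximum: no protein signal", call. = FALSE)
  a1 / a2
}

#' Signal-to-noise ratio of an unsmoothed difference spectrum
#'
#' S is the mean absorbance between 1540 and 1560 cm^-1 (bound-protein
#' Amide-II region); N is the root-mean-square of the absorbance between
#' 1800 and 1900 cm^-1, a protein-free window. Smoothing would deflate N, so
#' smoothed input is a contract violation.
#'
#' @param s an `ir_spectrum` carrying `meta$smoothed = FALSE`
#' @param signal_window,noise_window windows in cm^-1
#' @param mean_subtract subtract the window mean before the RMS (default
#'   `FALSE`: the literal root-mean-square of the absorbance values)
#' @return dimensionless S/N; `Inf` with a warning when N is exactly 0
#' @export
signal_to_noise <- function(s, signal_window = c(1540, 1560),
                            noise_window = c(1800, 1900),
                            mean_subtract = FALSE) {
  if (isTRUE(s$meta$smoothed))
    stop("signal_to_noise requires an unsmoothed spectrum", call. = FALSE)
  sig <- mean(s$absorbance[spec_window(s, signal_window)])
  nv <- s$absorbance[spec_window(s, noise_window)]
  if (mean_subtract) nv <- nv - mean(nv)
  n <- sqrt(mean(nv^2))
  if (n == 0) {
    warning("zero noise estimate: S/N reported as +Inf")
    return(Inf)
  }
  sig / n
}

#' Run both quality gates on a processed spectrum
#'
#' Gates (both closed-boundary): Amide-I/Amide-II ratio inside
#' \[1.10, 1.50\] and S/N >= 20. The ratio is evaluated on the processed
#' (smoothed) difference spectrum, S/N on its unsmoothed counterpart. A
#' spectrum whose Amide-II maximum is nonpositive fails the ratio gate
#' outright (no protein signal).
#'
#' @param s processed (smoothed) difference spectrum
#' @param s_unsmoothed the same difference spectrum before smoothing
#' @param ratio_range acceptance range of the Amide ratio
#' @param snr_min minimum S/N
#' @return a `qc_report` list: `amide_ratio`, `snr`, `passed`, `reasons`,
#'   `windows`
#' @export
run_qc <- function(s, s_unsmoothed, ratio_range = c(1.10, 1.50),
                   snr_min = 20) {
  ratio <- tryCatch(amide_ratio(s), error = function(e) NA_real_)
  snr <- signal_to_noise(s_unsmoothed)
  reasons <- character(0)
  if (is.na(ratio) || ratio < ratio_range[1] || ratio > ratio_range[2])
    reasons <- c(reasons, "amide_ratio")
  if (!(snr >= snr_min))
    reasons <- c(reasons, "snr")
  structure(list(amide_ratio = ratio, snr = snr,
                 passed = length(reasons) == 0L, reasons = reasons,
                 windows = list(ratio_range = ratio_range,
                                snr_min = snr_min)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> amide_ratio=%.3f snr=%.1f passed=%s%s\n",
              x$amide_ratio, x$snr, x$passed,
              if (length(x$reasons))
                paste0(" (", paste(x$reasons, collapse = ", "), ")")
              else ""))
  invisible(x)
}
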