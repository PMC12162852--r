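#' Construct an infrared spectrum
#'
#' The core data type of the package: a strictly monotonic wavenumber grid
#' (cm^-1) with matching absorbance values (AU) and a free-form metadata
#' list. Spectra are stored internally with a descending wavenumber grid
#' (FTIR plotting convention); ascending input is reordered and the original
#' orientation recorded in `meta$original_orientation`.
#'
#' @param wavenumbers numeric vector, strictly monotonic, length >= 2 (cm^-1)
#' @param absorbance numeric vector of the same length, all values finite (AU)
#' @param meta named list of free-form metadata (channel, subject id, stage
#'   tag, `smoothed` flag, processing trace, ...)
#' @return an object of class `ir_spectrum`
#' @export
ir_spectrum <- function(wavenumbers, absorbance, meta = list()) {
  if (!is.numeric(wavenumbers) || !is.numeric(absorbance))
    stop("wavenumbers and absorbance must be numeric", call. = FALSE)
  n <- length(wavenumbers)
  if (n < 2L)
    stop("a spectrum needs at least 2 points", call. = FALSE)
  if (length(absorbance) != n)
    stop("wavenumbers and absorbance differ in length (", n, " vs ",
         length(absorbance), ")", call. = FALSE)
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers)))
    stop("wavenumbers must be finite", call. = FALSE)
  if (anyNA(absorbance) || any(!is.finite(absorbance)))
    stop("absorbance values must be finite (no NA/NaN/Inf)", call. = FALSE)
  d <- diff(wavenumbers)
  if (all(d > 0)) {
    meta$original_orientation <- meta$original_orientation %||% "ascending"
    ord <- rev(seq_len(n))
    wavenumbers <- wavenumbers[ord]
    absorbance <- absorbance[ord]
  } else if (all(d < 0)) {
    meta$original_orientation <- meta$original_orientation %||% "descending"
  } else {
    stop("wavenumber grid must be strictly monotonic", call. = FALSE)
  }
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 absorbance = as.numeric(absorbance),
                 meta = meta),
            class = "ir_spectrum")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ir_spectrum <- function(x, ...) {
  rng <- range(x$wavenumbers)
  cat(sprintf("<ir_spectrum> %d points, %.1f-%.1f cm-1, A in [%.3g, %.3g]\n",
              length(x$wavenumbers), rng[2], rng[1],
              min(x$absorbance), max(x$absorbance)))
  tags <- setdiff(names(x$meta), "trace")
  if (length(tags))
    cat("  meta:", paste(tags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.ir_spectrum <- function(x, ...) {
  data.frame(wavenumber = x$wavenumbers, absorbance = x$absorbance)
}

#' @export
length.ir_spectrum <- function(x) length(x$wavenumbers)

#' Interpolated absorbance at arbitrary wavenumbers
#'
#' Linear interpolation between grid points; used for fractional-wavenumber
#' queries such as 1656.0 and 1623.5 cm^-1 on a 2 cm^-1 grid.
#'
#' @param s an `ir_spectrum`
#' @param nu numeric vector of query wavenumbers (cm^-1), inside the grid span
#' @return absorbance values at `nu`
#' @export
spec_at <- function(s, nu) {
  rng <- range(s$wavenumbers)
  if (any(nu < rng[1] | nu > rng[2]))
    stop("query wavenumber outside grid span [", rng[1], ", ", rng[2], "]",
         call. = FALSE)
  # approx requires ascending x
  stats::approx(rev(s$wavenumbers), rev(s$absorbance), xout = nu,
                method = "linear")$y
}

#' Indices of grid points inside a closed wavenumber window
#'
#' @param s an `ir_spectrum`
#' @param window numeric length-2, window bounds in cm^-1 (any order)
#' @return integer indices into the spectrum's grid
#' @export
spec_window <- function(s, window) {
  lo <- min(window); hi <- max(window)
  idx <- which(s$wavenumbers >= lo & s$wavenumbers <= hi)
  if (!length(idx))
    stop("window [", lo, ", ", hi, "] contains no grid points", call. = FALSE)
  idx
}

#' Test whether two spectra share one wavenumber grid
#' @param a,b `ir_spectrum` objects
#' @param tol absolute tolerance on grid positions
#' @return logical
#' @export
same_grid <- function(a, b, tol = 1e-9) {
  length(a$wavenumbers) == length(b$wavenumbers) &&
    all(abs(a$wavenumbers - b$wavenumbers) <= tol)
}

stop_if_grid_mismatch <- function(a, b, what = "spectra") {
  if (!same_grid(a, b))
    stop(what, " do not share a common wavenumber grid", call. = FALSE)
  invisible(TRUE)
}

#' Append a stage record to a spectrum's processing trace
#'
#' Every preprocessing stage records its name, parameters, and scalar
#' diagnostics in an append-only trace stored in `meta$trace`.
#'
#' @param s an `ir_spectrum`
#' @param stage character stage name
#' @param params named list of parameters/diagnostics
#' @return the spectrum with the trace extended
#' @export
add_trace <- function(s, stage, params = list()) {
  tr <- s$meta$trace %||% list()
  tr[[length(tr) + 1L]] <- list(stage = stage, params = params)
  s$meta$trace <- tr
  s
}

#' Retrieve the processing trace of a spectrum
#' @param s an `ir_spectrum`
#' @return list of stage records (possibly empty)
#' @export
get_trace <- function(s) s$meta$trace %||% list()

#' Default wavenumber grid
#'
#' Descending grid covering the analysis region used throughout: the Amide
#' bands (1700-1500 cm^-1), the noise window (1800-1900 cm^-1) and the
#' baseline anchor windows (1800-1750, 1490-1480 cm^-1). Spacing is
#' configurable; the instrument point spacing is not fixed by the assay.
#'
#' @param from,to grid limits in cm^-1
#' @param by grid spacing in cm^-1 (positive)
#' @return numeric descending grid
#' @export
default_grid <- function(from = 1900, to = 1480, by = 2) {
  seq(from, to, by = -abs(by))
}

# restore the caller's RNG state after running seeded code
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# deterministic 31-bit string hash used to fan one cohort seed out into
# per-subject substreams (insertion-order independent)
stable_hash <- function(x) {
  h <- 5381
  for (ch in utf8ToInt(x)) h <- (h * 33 + ch) %% 2147483629
  as.integer(h)
}

substream_seed <- function(seed, id) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + stable_hash(id)) %%
               2147483629)
}
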