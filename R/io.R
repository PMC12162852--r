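#' Read a two-column spectrum from CSV
#'
#' Expects rows of (wavenumber, absorbance). A single header line is allowed
#' and detected by non-numeric content. Two dialects are supported:
#' `"comma"` (comma delimiter, dot decimal mark; default) and `"semicolon"`
#' (semicolon delimiter, comma decimal mark).
#'
#' @param path file path
#' @param dialect `"comma"` or `"semicolon"`
#' @return an [ir_spectrum()]; the dialect used is recorded in `meta$dialect`
#' @export
read_spectrum_csv <- function(path, dialect = c("comma", "semicolon")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "comma") "," else ";"
  dec <- if (dialect == "comma") "." else ","
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty spectrum file: ", path, call. = FALSE)
  parse_line <- function(ln) {
    parts <- trimws(strsplit(ln, sep, fixed = TRUE)[[1]])
    if (dec != ".") parts <- gsub(dec, ".", parts, fixed = TRUE)
    suppressWarnings(as.numeric(parts))
  }
  first <- parse_line(lines[[1]])
  start <- 1L
  if (anyNA(first)) start <- 2L  # header line
  if (start > length(lines))
    stop("no data rows in spectrum file: ", path, call. = FALSE)
  rows <- lapply(lines[start:length(lines)], parse_line)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != 2L || anyNA(r))
      stop("cannot parse spectrum row at line ", start + i - 1L, " of ",
           path, call. = FALSE)
  }
  m <- do.call(rbind, rows)
  ir_spectrum(m[, 1], m[, 2],
              meta = list(source = path, dialect = dialect))
}

#' Write a spectrum to CSV
#'
#' Full-precision output (`%.17g`) so that write-then-read round trips are
#' exact.
#'
#' @param s an `ir_spectrum`
#' @param path output file
#' @param dialect see [read_spectrum_csv()]
#' @param header write a `wavenumber,absorbance` header line
#' @return `path`, invisibly
#' @export
write_spectrum_csv <- function(s, path, dialect = c("comma", "semicolon"),
                               header = TRUE) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "comma") "," else ";"
  dec <- if (dialect == "comma") "." else ","
  fmt <- function(x) {
    out <- sprintf("%.17g", x)
    if (dec != ".") out <- gsub(".", dec, out, fixed = TRUE)
    out
  }
  rows <- paste(fmt(s$wavenumbers), fmt(s$absorbance), sep = sep)
  if (header) rows <- c(paste("wavenumber", "absorbance", sep = sep), rows)
  writeLines(rows, path)
  invisible(path)
}

#' Read a single-block JCAMP-DX infrared spectrum
#'
#' Supports the two plain-text data layouts used for exchange of dispersive
#' and FT-IR spectra: `##XYDATA=(X++(Y..Y))` with AFFN (plain decimal)
#' ordinates, and `##XYPOINTS=(XY..XY)` pairs. `XFACTOR`/`YFACTOR` are
#' applied; for XYDATA the grid is reconstructed from
#' `FIRSTX`/`LASTX`/`NPOINTS`. Compressed ordinate forms (SQZ/DIF/DUP) and
#' multi-block compound files are not supported.
#'
#' @param path file path
#' @return an [ir_spectrum()]
#' @export
read_spectrum_jcampdx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_ldr <- grepl("^##", lines)
  if (sum(grepl("^##TITLE=", lines)) > 1L || any(grepl("^##BLOCKS=", lines)))
    stop("multi-block JCAMP-DX files are not supported", call. = FALSE)

  ldr_value <- function(label) {
    hit <- grep(paste0("^##", label, "="), lines)
    if (!length(hit)) return(NULL)
    sub(paste0("^##", label, "=\\s*"), "", lines[hit[1]])
  }
  num_ldr <- function(label, default = NULL) {
    v <- ldr_value(label)
    if (is.null(v)) return(default)
    as.numeric(v)
  }
  xfactor <- num_ldr("XFACTOR", 1)
  yfactor <- num_ldr("YFACTOR", 1)

  data_start <- grep("^##(XYDATA|XYPOINTS)=", lines)
  if (!length(data_start))
    stop("JCAMP-DX file has no XYDATA or XYPOINTS block: ", path,
         call. = FALSE)
  data_start <- data_start[1]
  kind <- if (grepl("^##XYDATA=", lines[data_start])) "XYDATA" else "XYPOINTS"
  block_end <- data_start + 1L
  while (block_end <= length(lines) && !is_ldr[block_end])
    block_end <- block_end + 1L
  body <- lines[seq(data_start + 1L, block_end - 1L)]
  body <- body[nzchar(trimws(body))]
  if (any(grepl("[A-DF-Za-df-z%@]", body)))
    stop("compressed (SQZ/DIF) JCAMP ordinates are not supported",
         call. = FALSE)
  toks <- function(x) {
    t <- unlist(strsplit(trimws(x), "[,;[:space:]]+"))
    t[nzchar(t)]
  }

  if (kind == "XYPOINTS") {
    vals <- suppressWarnings(as.numeric(toks(body)))
    if (anyNA(vals) || length(vals) %% 2L != 0L)
      stop("cannot parse XYPOINTS block in ", path, call. = FALSE)
    x <- vals[seq(1, length(vals), by = 2)] * xfactor
    y <- vals[seq(2, length(vals), by = 2)] * yfactor
  } else {
    firstx <- num_ldr("FIRSTX")
    lastx <- num_ldr("LASTX")
    npoints <- num_ldr("NPOINTS")
    if (is.null(firstx) || is.null(lastx) || is.null(npoints))
      stop("XYDATA requires FIRSTX, LASTX and NPOINTS labels", call. = FALSE)
    ys <- numeric(0)
    for (ln in body) {
      v <- suppressWarnings(as.numeric(toks(ln)))
      if (anyNA(v)) stop("cannot parse XYDATA line: ", ln, call. = FALSE)
      ys <- c(ys, v[-1])  # leading token is the line's X check value
    }
    if (length(ys) != npoints)
      stop("XYDATA ordinate count (", length(ys), ") does not match NPOINTS (",
           npoints, ")", call. = FALSE)
    x <- seq(firstx, lastx, length.out = npoints) * xfactor
    y <- ys * yfactor
  }
  ir_spectrum(x, y, meta = list(source = path, format = "jcampdx",
                                title = ldr_value("TITLE")))
}

#' Write a spectrum as JCAMP-DX (AFFN XYDATA)
#'
#' Ordinates are quantized to integer multiples of `YFACTOR`; the default
#' factor keeps the quantization error below `max(abs(A))/2e7`, i.e. well
#' under 1e-6 AU for any physically plausible absorbance scale.
#'
#' @param s an `ir_spectrum`
#' @param path output file
#' @param title JCAMP TITLE field
#' @param yfactor ordinate quantum; default `max(abs(A))/1e7` (or 1 for an
#'   all-zero spectrum)
#' @return `path`, invisibly
#' @export
write_spectrum_jcampdx <- function(s, path, title = "irsyn spectrum",
                                   yfactor = NULL) {
  x <- s$wavenumbers
  y <- s$absorbance
  if (is.null(yfactor)) {
    m <- max(abs(y))
    yfactor <- if (m > 0) m / 1e7 else 1
  }
  yi <- round(y / yfactor)
  n <- length(x)
  dx <- (x[n] - x[1]) / (n - 1)
  hdr <- c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=4.24",
    "##DATA TYPE=INFRARED SPECTRUM",
    "##XUNITS=1/CM",
    "##YUNITS=ABSORBANCE",
    "##XFACTOR=1",
    sprintf("##YFACTOR=%.17g", yfactor),
    sprintf("##FIRSTX=%.17g", x[1]),
    sprintf("##LASTX=%.17g", x[n]),
    sprintf("##DELTAX=%.17g", dx),
    sprintf("##NPOINTS=%d", n),
    "##XYDATA=(X++(Y..Y))"
  )
  per_line <- 8L
  body <- character(0)
  i <- 1L
  while (i <= n) {
    j <- min(i + per_line - 1L, n)
    body <- c(body, paste(c(sprintf("%.17g", x[i]),
                            format(yi[i:j], scientific = FALSE, trim = TRUE)),
                          collapse = " "))
    i <- j + 1L
  }
  writeLines(c(hdr, body, "##END="), path)
  invisible(path)
}

.diagnosis_vocab <- c("PD", "MSA", "CBD", "FTD", "PSP", "control", "other")

#' Derive the misfolding group from a clinical diagnosis
#'
#' PD and MSA are synucleinopathies and form the misfolding-positive group;
#' all other accepted diagnoses (atypical Parkinsonian syndromes, dementias,
#' disease controls) form the control group.
#'
#' @param diagnosis character vector with values in
#'   `PD, MSA, CBD, FTD, PSP, control, other`
#' @return factor with levels `misfolding_positive`, `control`
#' @export
derive_group <- function(diagnosis) {
  bad <- setdiff(unique(diagnosis), .diagnosis_vocab)
  if (length(bad))
    stop("unknown diagnosis value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  factor(ifelse(diagnosis %in% c("PD", "MSA"), "misfolding_positive",
                "control"),
         levels = c("misfolding_positive", "control"))
}

#' Read a cohort table (subject metadata)
#'
#' Accepts TSV or CSV (sniffed from the header line) with mandatory columns
#' `subject_id`, `diagnosis`, `age`, `sex` and an optional `q_alb`
#' (CSF/serum albumin quotient x 10^3). Diagnoses outside the accepted
#' vocabulary are rejected with their row number; the misfolding group is
#' derived with [derive_group()].
#'
#' @param path file path
#' @return data.frame of subject records with a derived `group` column
#' @export
read_cohort_table <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", "-",
                                                                   ""))
  need <- c("subject_id", "diagnosis", "age", "sex")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("cohort table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!(df$diagnosis %in% .diagnosis_vocab))
  if (length(bad))
    stop("unknown diagnosis '", df$diagnosis[bad[1]], "' at data row ",
         bad[1], call. = FALSE)
  bad_sex <- which(!(df$sex %in% c("F", "M")))
  if (length(bad_sex))
    stop("sex must be F or M (data row ", bad_sex[1], ")", call. = FALSE)
  if (any(!is.finite(df$age)) || any(df$age <= 0))
    stop("age must be a positive number for every subject", call. = FALSE)
  df$group <- derive_group(df$diagnosis)
  if (!"q_alb" %in% names(df)) df$q_alb <- NA_real_
  df[c("subject_id", "diagnosis", "group", "age", "sex", "q_alb")]
}

#' Write a cohort table as TSV
#' @param records cohort data.frame (as returned by [read_cohort_table()] or
#'   [simulate_cohort()])
#' @param path output file
#' @return `path`, invisibly
#' @export
write_cohort_table <- function(records, path) {
  cols <- intersect(c("subject_id", "diagnosis", "age", "sex", "q_alb"),
                    names(records))
  utils::write.table(records[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
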