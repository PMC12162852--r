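#' Classification thresholds on the 1656.0/1623.5 ratio
#'
#' The single decision threshold and the traffic-light pair bracketing the
#' intermediate (at-risk) zone.
#'
#' @param lower red/yellow boundary (high misfolding below)
#' @param single single-threshold decision point
#' @param upper yellow/green boundary (low misfolding above)
#' @return a `thresholds` list; requires `lower < single < upper`
#' @export
ratio_thresholds <- function(lower = 1.065, single = 1.093, upper = 1.14) {
  if (!(lower < single && single < upper))
    stop("thresholds must satisfy lower < single < upper", call. = FALSE)
  structure(list(lower = lower, single = single, upper = upper),
            class = "thresholds")
}

#' Single-threshold classification
#'
#' Ratios below the threshold indicate misfolding. A ratio exactly at the
#' threshold is classified negative (documented boundary rule).
#'
#' @param ratio numeric vector of 1656.0/1623.5 ratios (> 0; `NA` allowed
#'   for invalid features and propagated)
#' @param threshold decision threshold
#' @return character vector of `"positive"`/`"negative"` (`NA` preserved)
#' @export
classify_single <- function(ratio, threshold = 1.093) {
  ifelse(is.na(ratio), NA_character_,
         ifelse(ratio < threshold, "positive", "negative"))
}

#' Traffic-light classification
#'
#' Ratio strictly below `lower` is red (high misfolding, clear
#' synucleinopathy affliction); strictly above `upper` is green (low
#' misfolding); anything in the closed interval between is yellow
#' (intermediate, at risk). Values equal to either threshold are yellow.
#'
#' @param ratio numeric vector (`NA` preserved)
#' @param thresholds a [ratio_thresholds()]
#' @return factor with levels `red`, `yellow`, `green`
#' @export
classify_traffic_light <- function(ratio, thresholds = ratio_thresholds()) {
  lab <- ifelse(is.na(ratio), NA_character_,
                ifelse(ratio < thresholds$lower, "red",
                       ifelse(ratio > thresholds$upper, "green", "yellow")))
  factor(lab, levels = c("red", "yellow", "green"))
}

#' Round half-up
#'
#' Rounding convention used for reported percentages (e.g. sensitivity and
#' specificity), where halves round away from zero for positive values.
#'
#' @param x numeric
#' @return `floor(x + 0.5)`
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Confusion table from counts
#'
#' Sensitivity and specificity in percent; the reported values are rounded
#' half-up to integers (matching the printed precision) while raw fractions
#' are retained.
#'
#' @param tp,fn,fp,tn nonnegative counts
#' @return a `confusion_table` list
#' @export
confusion_from_counts <- function(tp, fn, fp, tn) {
  if (any(c(tp, fn, fp, tn) < 0)) stop("counts must be >= 0", call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0)
    stop("metrics undefined: a truth class has no subjects", call. = FALSE)
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn,
                 sensitivity = round_half_up(sens),
                 specificity = round_half_up(spec),
                 sensitivity_raw = sens, specificity_raw = spec),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf(paste0("<confusion_table> tp=%d fn=%d fp=%d tn=%d  ",
                     "sensitivity=%d%% specificity=%d%%\n"),
              x$tp, x$fn, x$fp, x$tn, x$sensitivity, x$specificity))
  invisible(x)
}

#' Confusion metrics from the extreme traffic-light groups
#'
#' Yellow (intermediate) subjects are excluded; red counts as test-positive
#' and green as test-negative against the clinical truth (PD/MSA =
#' misfolding positive).
#'
#' @param labels traffic-light labels (factor from
#'   [classify_traffic_light()]); `NA` labels are excluded and counted
#' @param group truth groups (factor with levels `misfolding_positive`,
#'   `control`)
#' @return a `confusion_table` with additional fields `n_yellow` and
#'   `n_invalid`
#' @export
confusion_from_extremes <- function(labels, group) {
  stopifnot(length(labels) == length(group))
  invalid <- is.na(labels)
  keep <- !invalid & labels != "yellow"
  lab <- labels[keep]
  grp <- group[keep]
  pos <- grp == "misfolding_positive"
  ct <- confusion_from_counts(tp = sum(lab == "red" & pos),
                              fn = sum(lab == "green" & pos),
                              fp = sum(lab == "red" & !pos),
                              tn = sum(lab == "green" & !pos))
  ct$n_yellow <- sum(!invalid & labels == "yellow")
  ct$n_invalid <- sum(invalid)
  ct
}
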