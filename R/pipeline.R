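#' Full-run configuration
#'
#' Bundles the generator configuration with every stage parameter of the
#' analysis so that one object determines a pipeline run completely.
#'
#' @param cohort a [cohort_config()]
#' @param thresholds a [ratio_thresholds()]
#' @param smooth_window,smooth_polyorder Savitzky-Golay parameters
#' @param com_fraction threshold fraction for the center-of-mass maximum
#' @param ratio_range,snr_min quality gates
#' @return a `run_config` list
#' @export
run_config <- function(cohort, thresholds = ratio_thresholds(),
                       smooth_window = 9, smooth_polyorder = 3,
                       com_fraction = 0.85,
                       ratio_range = c(1.10, 1.50), snr_min = 20) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(thresholds, "thresholds"))
  structure(list(cohort = cohort, thresholds = thresholds,
                 smooth_window = smooth_window,
                 smooth_polyorder = smooth_polyorder,
                 com_fraction = com_fraction,
                 ratio_range = ratio_range, snr_min = snr_min),
            class = "run_config")
}

#' Run the complete analysis pipeline on a synthetic cohort
#'
#' simulate -> process -> qc -> features -> classify -> analyze, as a pure
#' function of the configuration (including its seed). Subjects failing
#' either quality gate are excluded from features and statistics and
#' counted; every reported n is post-QC.
#'
#' @param config a [run_config()] (or a bare [cohort_config()], which is
#'   wrapped with default stage parameters)
#' @param out_dir optional directory; when given, the cohort table, feature
#'   table, label table and a metrics JSON are written there
#' @return a `run_report` list: `records` (with features and labels), `qc`,
#'   `group_difference`, `integrals`, `stats`, `confusion`, `counts`,
#'   `config`
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (inherits(config, "cohort_config")) config <- run_config(config)
  stopifnot(inherits(config, "run_config"))
  cc <- config$cohort
  if (cc$n_positive < 1 || cc$n_control < 1)
    stop("pipeline statistics require at least one subject per group",
         call. = FALSE)
  sim <- simulate_cohort(cc)
  records <- sim$records
  vref <- vapor_reference(cc$grid)

  n <- nrow(records)
  qc_list <- vector("list", n)
  feats <- data.frame(subject_id = records$subject_id,
                      abs_max = NA_real_, com_max = NA_real_,
                      ratio = NA_real_, kinetic_amplitude = NA_real_,
                      qc_passed = FALSE, qc_reasons = "",
                      stringsAsFactors = FALSE)
  diffs <- vector("list", n)
  for (i in seq_len(n)) {
    run <- sim$runs[[records$subject_id[i]]]
    proc <- process_run(run, vapor_ref = vref,
                        smooth_window = config$smooth_window,
                        smooth_polyorder = config$smooth_polyorder)
    qc <- run_qc(proc$difference, proc$difference_raw,
                 ratio_range = config$ratio_range, snr_min = config$snr_min)
    qc_list[[i]] <- qc
    feats$qc_passed[i] <- qc$passed
    feats$qc_reasons[i] <- paste(qc$reasons, collapse = ";")
    if (qc$passed) {
      fs <- extract_features(proc, qc = qc, kinetics = run$kinetics,
                             com_fraction = config$com_fraction)
      feats$abs_max[i] <- fs$abs_max
      feats$com_max[i] <- fs$com_max
      feats$ratio[i] <- fs$ratio_1656_1623
      feats$kinetic_amplitude[i] <- fs$kinetic_amplitude
      diffs[[i]] <- proc$difference
    }
  }
  records <- cbind(records, feats[-1])
  records$label <- classify_traffic_light(records$ratio, config$thresholds)
  records$single_call <- classify_single(records$ratio,
                                         config$thresholds$single)

  ok <- records$qc_passed & !is.na(records$ratio)
  pos <- ok & records$group == "misfolding_positive"
  ctl <- ok & records$group == "control"
  if (!any(pos) || !any(ctl))
    stop("no QC-passing subjects left in one of the groups", call. = FALSE)

  gd <- group_difference(diffs[pos], diffs[ctl])
  integrals <- band_integrals(gd)

  analysis_rec <- records[ok, , drop = FALSE]
  fit <- fit_logistic_score(analysis_rec)
  combined_roc <- roc_auc(fit$scores, analysis_rec$group)
  cov_roc <- covariate_only_auc(analysis_rec)
  mwu <- mann_whitney_u(analysis_rec$ratio[analysis_rec$group ==
                                             "misfolding_positive"],
                        analysis_rec$ratio[analysis_rec$group == "control"])
  sex_tab <- table(analysis_rec$group, analysis_rec$sex)
  chi <- if (all(dim(sex_tab) == c(2, 2)) && all(rowSums(sex_tab) > 0) &&
             all(colSums(sex_tab) > 0)) chi_square_sex(sex_tab) else NULL
  confusion <- tryCatch(
    confusion_from_extremes(records$label[ok], records$group[ok]),
    error = function(e) NULL)

  label_counts <- table(records$label[ok])
  counts <- list(
    n_total = n, n_qc_excluded = sum(!records$qc_passed),
    n_invalid_ratio = sum(records$qc_passed & is.na(records$ratio)),
    n_analyzed = sum(ok),
    n_positive = sum(pos), n_control = sum(ctl),
    labels = as.list(label_counts))

  medians <- tapply(analysis_rec$ratio, analysis_rec$group, stats::median)
  com_means <- tapply(analysis_rec$com_max, analysis_rec$group, mean)

  report <- structure(list(
    records = records, qc = qc_list, group_difference = gd,
    integrals = integrals,
    stats = list(combined_roc = combined_roc, covariate_roc = cov_roc,
                 mwu = mwu, chi_square_sex = chi,
                 median_ratio = medians, mean_com_max = com_means,
                 logistic = fit[c("coefficients", "separation",
                                  "n_excluded")]),
    confusion = confusion, counts = counts, config = config),
    class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_table(records, file.path(out_dir, "cohort.tsv"))
    utils::write.table(
      records[c("subject_id", "abs_max", "com_max", "ratio", "qc_passed",
                "qc_reasons", "label", "single_call")],
      file.path(out_dir, "features.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(report_metrics(report),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# flatten the numeric results of a run for JSON serialization
report_metrics <- function(report) {
  s <- report$stats
  list(
    counts = report$counts,
    median_ratio = as.list(s$median_ratio),
    mean_com_max = as.list(s$mean_com_max),
    combined_auc = s$combined_roc$auc,
    combined_auc_ci = c(s$combined_roc$ci_low, s$combined_roc$ci_high),
    covariate_only_auc = s$covariate_roc$auc,
    mwu_p = s$mwu$p_value,
    integrals = report$integrals[c("positive_integral",
                                   "negative_integral")],
    confusion = if (!is.null(report$confusion))
      report$confusion[c("tp", "fn", "fp", "tn", "sensitivity",
                         "specificity")] else NULL)
}

#' Human-readable pipeline summary
#'
#' @param report a `run_report` from [run_pipeline()]
#' @return character vector of report lines
#' @export
make_report <- function(report) {
  stopifnot(inherits(report, "run_report"))
  s <- report$stats
  cn <- report$counts
  lab <- cn$labels
  lines <- c(
    "== iRS misfolding analysis ==",
    sprintf("subjects: %d (excluded by QC: %d, invalid ratio: %d)",
            cn$n_total, cn$n_qc_excluded, cn$n_invalid_ratio),
    sprintf("analyzed: %d (%d misfolding-positive / %d control)",
            cn$n_analyzed, cn$n_positive, cn$n_control),
    sprintf("traffic light: red %d / yellow %d / green %d",
            lab$red %||% 0, lab$yellow %||% 0, lab$green %||% 0),
    sprintf("median 1656.0/1623.5 ratio: positives %.3f, controls %.3f",
            s$median_ratio[["misfolding_positive"]],
            s$median_ratio[["control"]]),
    sprintf("Mann-Whitney U = %.1f, p = %.3g", s$mwu$statistic,
            s$mwu$p_value),
    sprintf("logistic ROC AUC (ratio + age + sex): %.3f (95%% CI %.3f-%.3f)",
            s$combined_roc$auc, s$combined_roc$ci_low,
            s$combined_roc$ci_high),
    sprintf("covariate-only AUC (age + sex): %.3f", s$covariate_roc$auc),
    if (!is.null(report$confusion))
      sprintf(paste0("extremes (red vs green): sensitivity %d%%, ",
                     "specificity %d%% (tp=%d fn=%d fp=%d tn=%d)"),
              report$confusion$sensitivity, report$confusion$specificity,
              report$confusion$tp, report$confusion$fn, report$confusion$fp,
              report$confusion$tn)
    else "extremes: undefined (no extreme-group subjects)")
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat(make_report(x), sep = "\n")
  invisible(x)
}
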