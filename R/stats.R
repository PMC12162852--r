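#' Two-sided Mann-Whitney U test
#'
#' Wraps the Wilcoxon rank-sum machinery: the exact null distribution is
#' used for small tie-free samples (min group size <= 8), the normal
#' approximation with tie correction otherwise. The statistic is reported in
#' the min orientation `U = min(U_xy, U_yx)`.
#'
#' @param x,y numeric samples (each nonempty)
#' @param exact_max largest min-group size for the exact branch
#' @return a `group_test` list: `statistic` (U), `p_value`, `method`, `n`
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  if (!length(x) || !length(y))
    stop("both groups must be nonempty", call. = FALSE)
  if (length(unique(c(x, y))) == 1L) {
    warning("all values identical across both groups: p = 1")
    return(structure(list(statistic = length(x) * length(y) / 2, p_value = 1,
                          method = "degenerate", n = c(length(x), length(y))),
                     class = "group_test"))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && min(length(x), length(y)) <= exact_max
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  u_xy <- unname(ht$statistic)
  u <- min(u_xy, length(x) * length(y) - u_xy)
  structure(list(statistic = u, p_value = ht$p.value,
                 method = if (exact) "exact" else "normal_approx_ties",
                 n = c(length(x), length(y))),
            class = "group_test")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Used for the per-group sex distribution. No continuity correction by
#' default; the Yates-corrected variant is available behind a flag.
#'
#' @param counts 2x2 matrix of counts
#' @param correct apply continuity correction
#' @return a `group_test` list
#' @export
chi_square_sex <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)))
    stop("a 2x2 table of counts is required", call. = FALSE)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in the 2x2 table", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  structure(list(statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 method = if (correct) "pearson_continuity" else "pearson",
                 n = sum(counts)),
            class = "group_test")
}

#' Logistic scoring of disease status
#'
#' Maximum-likelihood logistic regression of the misfolding-positive status
#' on the requested covariates (by default the spectral ratio, age and sex;
#' sex is coded F = 1, M = 0). Subjects with missing covariates are excluded
#' and counted. Under perfect separation (or non-convergence) the score
#' falls back to the rank of the linear predictor — a monotone equivalent
#' that keeps the ROC computable — with an explicit warning.
#'
#' @param records data.frame with columns `group` plus the covariates
#' @param covariates character vector of covariate column names (nonempty)
#' @return list with `scores` (predicted probability of disease, NA for
#'   excluded subjects), `coefficients`, `n_excluded`, `separation`
#' @export
fit_logistic_score <- function(records,
                               covariates = c("ratio", "age", "sex")) {
  if (!length(covariates))
    stop("at least one covariate is required", call. = FALSE)
  missing_cols <- setdiff(c("group", covariates), names(records))
  if (length(missing_cols))
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- records
  df$.y <- as.integer(df$group == "misfolding_positive")
  if (length(unique(df$.y[!is.na(df$.y)])) < 2L)
    stop("both classes must be present", call. = FALSE)
  if ("sex" %in% covariates)
    df$sex <- as.integer(df$sex == "F")
  complete <- stats::complete.cases(df[c(".y", covariates)])
  n_excluded <- sum(!complete)
  fit_df <- df[complete, , drop = FALSE]
  if (min(table(fit_df$.y)) < 2L)
    stop("need at least 2 subjects per class with complete covariates",
         call. = FALSE)
  fml <- stats::as.formula(paste(".y ~", paste(covariates, collapse = " + ")))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = fit_df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  scores <- rep(NA_real_, nrow(df))
  if (sep) {
    warning("separation detected: scores fall back to the rank of the ",
            "linear predictor")
    lp <- stats::predict(fit, newdata = fit_df, type = "link")
    scores[complete] <- rank(lp) / (length(lp) + 1)
  } else {
    scores[complete] <- stats::predict(fit, newdata = fit_df,
                                       type = "response")
  }
  list(scores = scores, coefficients = stats::coef(fit),
       n_excluded = n_excluded, separation = sep)
}

#' Empirical ROC curve and AUC with DeLong confidence interval
#'
#' The AUC is the trapezoidal area under the empirical ROC, equal to the
#' normalized Mann-Whitney U statistic; the 95% interval uses the DeLong
#' method by default, a seeded bootstrap behind a flag. The score direction
#' is fixed: higher scores indicate the positive class (the curve is never
#' silently flipped).
#'
#' @param scores numeric scores, higher = more disease-like
#' @param truth logical or factor truth; `TRUE`/`"misfolding_positive"` is
#'   the positive class
#' @param ci_method `"delong"` or `"bootstrap"`
#' @param boot_n bootstrap replicates
#' @return a `roc_result` list: `auc`, `ci_low`, `ci_high`, `curve`
#'   (data.frame `fpr`, `tpr`), `n`
#' @export
roc_auc <- function(scores, truth, ci_method = c("delong", "bootstrap"),
                    boot_n = 2000) {
  ci_method <- match.arg(ci_method)
  if (is.factor(truth) || is.character(truth))
    truth <- truth == "misfolding_positive"
  keep <- !is.na(scores) & !is.na(truth)
  scores <- scores[keep]; truth <- truth[keep]
  if (!any(truth) || all(truth))
    stop("both classes must be present", call. = FALSE)
  r <- pROC::roc(response = truth, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- withCallingHandlers(
    if (ci_method == "delong") pROC::ci.auc(r, method = "delong")
    else pROC::ci.auc(r, method = "bootstrap", boot.n = boot_n,
                      progress = "none"),
    warning = function(w) {
      # informational only: a degenerate interval at AUC == 1
      if (grepl("always 1-1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci_low = ci[1], ci_high = ci[3],
                 curve = data.frame(fpr = 1 - r$specificities,
                                    tpr = r$sensitivities),
                 ci_method = ci_method,
                 n = c(positive = sum(truth), control = sum(!truth))),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f, %s), n=%d/%d\n",
              x$auc, x$ci_low, x$ci_high, x$ci_method,
              x$n["positive"], x$n["control"]))
  invisible(x)
}

#' AUC of the demographics-only model
#'
#' Logistic scoring on age and sex alone, quantifying how much of the
#' discrimination is attributable to the covariates rather than the
#' spectral read-out.
#'
#' @param records data.frame with `group`, `age`, `sex`
#' @return a `roc_result`
#' @export
covariate_only_auc <- function(records) {
  fit <- fit_logistic_score(records, covariates = c("age", "sex"))
  roc_auc(fit$scores, records$group)
}

#' Age-dependent albumin-quotient positivity
#'
#' Blood-brain-barrier dysfunction is indicated when the CSF/serum albumin
#' quotient exceeds the age-dependent norm `4 + age/15` (strict inequality).
#'
#' @param age years (> 0)
#' @param q_alb CSF/serum albumin quotient (x 10^3)
#' @return logical vector (`NA` for missing quotients)
#' @export
qalb_positivity <- function(age, q_alb) {
  if (any(age <= 0, na.rm = TRUE)) stop("age must be > 0", call. = FALSE)
  q_alb > 4 + age / 15
}

#' Antibody extraction efficiency from ELISA concentrations
#'
#' Percent reduction of the analyte concentration after circulation over the
#' capture surface.
#'
#' @param original_conc concentration of the original sample (> 0)
#' @param supernatant_conc concentration of the collected supernatant (>= 0)
#' @return percent; negative (with a warning) when the supernatant exceeds
#'   the original, which suggests a dilution mismatch
#' @export
extraction_efficiency <- function(original_conc, supernatant_conc) {
  if (original_conc <= 0) stop("original concentration must be > 0",
                               call. = FALSE)
  if (supernatant_conc < 0) stop("supernatant concentration must be >= 0",
                                 call. = FALSE)
  eff <- 100 * (original_conc - supernatant_conc) / original_conc
  if (eff < 0)
    warning("supernatant exceeds original concentration: ",
            "possible dilution mismatch")
  eff
}

#' Thioflavin T aggregation verdict
#'
#' Material is called aggregated when the excitation maximum sits within
#' 3 nm of 450 nm (intercalated dye; free dye peaks at 413 nm) and the mean
#' emission at 482 nm is at least 20x the blank.
#'
#' @param excitation data.frame (`wavelength`, `intensity`), 410-460 nm
#' @param emission data.frame (`wavelength`, `intensity`), 480-620 nm
#' @param blank blank emission scan, same layout as `emission`
#' @return list: `peak_shift_nm` (excitation argmax), `emission_factor`,
#'   `aggregated`
#' @export
tht_verdict <- function(excitation, emission, blank) {
  ex_peak <- excitation$wavelength[which.max(excitation$intensity)]
  at482 <- function(df) stats::approx(df$wavelength, df$intensity,
                                      xout = 482)$y
  b <- at482(blank)
  if (is.na(b) || b == 0)
    stop("blank emission at 482 nm is zero or unavailable", call. = FALSE)
  factor <- at482(emission) / b
  list(peak_shift_nm = ex_peak, emission_factor = factor,
       aggregated = abs(ex_peak - 450) <= 3 && factor >= 20)
}
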