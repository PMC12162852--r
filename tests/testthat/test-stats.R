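test_that("the exact Mann-Whitney branch matches brute-force enumeration", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$method, "exact")
  oracle <- brute_mwu(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, oracle$p)

  set.seed(11)
  for (i in 1:12) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- round(stats::runif(n1), 6); y <- round(stats::runif(n2, 0.3), 6)
    res <- mann_whitney_u(x, y)
    oracle <- brute_mwu(x, y)
    expect_equal(res$statistic, oracle$u_min)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  }
})

test_that("tied and degenerate inputs are handled explicitly", {
  expect_warning(res <- mann_whitney_u(c(2, 2, 2), c(2, 2, 2)), "identical")
  expect_equal(res$p_value, 1)

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$method, "normal_approx_ties")
  expect_equal(same$statistic, 4.5)
  expect_gt(same$p_value, 0.8)
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("the rank-sum test holds its nominal size", {
  set.seed(271828)
  n_rep <- 10000
  rejections <- 0L
  for (i in seq_len(n_rep)) {
    pooled <- stats::rnorm(24)
    p <- mann_whitney_u(pooled[1:12], pooled[13:24])$p_value
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_lt(abs(rejections / n_rep - 0.05), 0.01)
})

test_that("the Pearson chi-square matches hand computation and scales", {
  balanced <- matrix(c(10, 10, 10, 10), 2)
  res <- chi_square_sex(balanced)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  tab <- matrix(c(10, 20, 10, 0), 2)  # rows (10,10) and (20,0)
  expect_equal(chi_square_sex(tab)$statistic, 40 / 3)
  expect_equal(chi_square_sex(2 * tab)$statistic, 80 / 3)
  expect_error(chi_square_sex(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("logistic scoring is null-calibrated and survives separation", {
  set.seed(99)
  n <- 1000
  rec <- data.frame(
    group = factor(rep(c("misfolding_positive", "control"), each = n / 2),
                   levels = c("misfolding_positive", "control")),
    ratio = stats::rnorm(n), age = stats::rnorm(n, 70, 8),
    sex = sample(c("F", "M"), n, replace = TRUE))
  fit <- fit_logistic_score(rec)
  expect_lt(abs(unname(fit$coefficients["ratio"])), 0.25)
  expect_lt(abs(roc_auc(fit$scores, rec$group)$auc - 0.5), 0.06)

  sep <- rec[c(1:30, 501:530), ]
  sep$ratio <- ifelse(sep$group == "misfolding_positive",
                      stats::runif(60, 0.9, 1.0), stats::runif(60, 1.1, 1.3))
  expect_warning(sfit <- fit_logistic_score(sep), "separation")
  expect_equal(roc_auc(sfit$scores, sep$group)$auc, 1.0)
})

test_that("the empirical AUC equals the normalized U statistic", {
  expect_equal(roc_auc(c(0, 0, 1, 1),
                       c(FALSE, FALSE, TRUE, TRUE))$auc, 1.0)
  set.seed(314)
  for (i in 1:100) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    scores <- if (i %% 3 == 0)
      sample(1:8, n1 + n2, replace = TRUE)  # heavy ties
    else stats::rnorm(n1 + n2)
    truth <- c(rep(TRUE, n1), rep(FALSE, n2))
    auc <- roc_auc(scores, truth)$auc
    u <- sum(outer(scores[truth], scores[!truth], ">")) +
      0.5 * sum(outer(scores[truth], scores[!truth], "=="))
    expect_equal(auc, u / (n1 * n2), tolerance = 1e-12)
  }
})

test_that("roc_auc validates inputs and reports a DeLong interval", {
  set.seed(7)
  scores <- stats::rnorm(200) + rep(c(1, 0), each = 100)
  truth <- rep(c(TRUE, FALSE), each = 100)
  r <- roc_auc(scores, truth)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  expect_true(all(diff(r$curve$fpr) >= 0) || all(diff(r$curve$fpr) <= 0))
  expect_error(roc_auc(scores, rep(TRUE, 200)), "both classes")
})

test_that("the demographics-only model discriminates only when the
           demographics differ", {
  set.seed(55)
  n <- 1000
  balanced <- data.frame(
    group = factor(rep(c("misfolding_positive", "control"), each = n / 2),
                   levels = c("misfolding_positive", "control")),
    age = stats::rnorm(n, 70, 8),
    sex = sample(c("F", "M"), n, replace = TRUE))
  expect_lt(abs(covariate_only_auc(balanced)$auc - 0.5), 0.06)

  sex <- c(sample(c("F", "M"), n / 2, TRUE, prob = c(0.23, 0.77)),
           sample(c("F", "M"), n / 2, TRUE, prob = c(0.53, 0.47)))
  imbalanced <- data.frame(group = balanced$group, age = balanced$age,
                           sex = sex)
  expect_gt(covariate_only_auc(imbalanced)$auc, 0.5)
  expect_error(fit_logistic_score(balanced, covariates = character(0)),
               "at least one covariate")
})

test_that("albumin-quotient positivity applies the age-dependent norm", {
  expect_true(qalb_positivity(60, 8.1))    # norm 8.0
  expect_false(qalb_positivity(75, 9.0))   # norm 9.0, strict >
  expect_false(qalb_positivity(30, 5.9))   # norm 6.0
  expect_true(is.na(qalb_positivity(60, NA)))
  expect_error(qalb_positivity(-1, 5), "age")
})

test_that("extraction efficiency is plain percent reduction with a dilution
           warning", {
  expect_equal(extraction_efficiency(1197, 161), 100 * (1197 - 161) / 1197)
  expect_gt(extraction_efficiency(1197, 161), 85)
  expect_equal(round(extraction_efficiency(1197, 1075), 1), 10.2)
  expect_equal(extraction_efficiency(500, 500), 0)
  expect_warning(v <- extraction_efficiency(100, 120), "dilution")
  expect_lt(v, 0)
})

test_that("the ThT verdict enforces both printed criteria inclusively", {
  ex <- data.frame(wavelength = 410:460,
                   intensity = 1 + 100 * exp(-((410:460 - 450) / 10)^2))
  em <- data.frame(wavelength = 480:620, intensity = rep(2000, 141))
  blank <- data.frame(wavelength = 480:620, intensity = rep(100, 141))
  v <- tht_verdict(ex, em, blank)
  expect_equal(v$emission_factor, 20)
  expect_true(v$aggregated)  # factor exactly 20 counts as aggregated

  ex413 <- data.frame(wavelength = 410:460,
                      intensity = 1 + 100 * exp(-((410:460 - 413) / 10)^2))
  expect_false(tht_verdict(ex413, em, blank)$aggregated)
  zero_blank <- data.frame(wavelength = 480:620, intensity = rep(0, 141))
  expect_error(tht_verdict(ex, em, zero_blank), "blank")
})
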