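mk_truth <- function(n_left, n_right, n_hc, n_dc) {
  tibble::tibble(
    subject_id = sprintf("e%03d", seq_len(n_left + n_right + n_hc + n_dc)),
    group = c(rep("patient_HS", n_left + n_right),
              rep("healthy_control", n_hc), rep("disease_control", n_dc)),
    lateralization = c(rep("left", n_left), rep("right", n_right),
                       rep("none", n_hc + n_dc)),
    age_years = 30, sex = "F", site_id = "A")
}

test_that("sensitivity and specificity are plain correct fractions", {
  truth <- mk_truth(12, 12, 20, 10)
  pred <- tibble::tibble(
    subject_id = truth$subject_id,
    detection = "HS",
    lateralization = truth$lateralization)
  pred$lateralization[pred$lateralization == "none"] <- "left"
  # 19 of 24 patients detected
  pred$detection[1:5] <- "noHS"
  pred$detection[25:54] <- "noHS"
  pf <- performance(pred, truth)$overall
  expect_equal(pf$detection_pct, 100 * 19 / 24, tolerance = 1e-12)
  expect_equal(round(pf$detection_pct, 1), 79.2)
  expect_equal(pf$specificity_pct, 100)
  expect_equal(pf$lateralization_pct, 100)

  # perfect predictor
  perfect <- tibble::tibble(subject_id = truth$subject_id,
                            detection = ifelse(truth$group == "patient_HS", "HS", "noHS"),
                            lateralization = ifelse(truth$lateralization == "none",
                                                    "left", truth$lateralization))
  pfp <- performance(perfect, truth)$overall
  expect_equal(unlist(pfp[c("detection_pct", "lateralization_pct", "specificity_pct")]),
               c(100, 100, 100), ignore_attr = TRUE)

  # degenerate all-noHS predictor
  none <- perfect
  none$detection <- "noHS"
  pfn <- performance(none, truth)$overall
  expect_equal(pfn$detection_pct, 0)
  expect_equal(pfn$specificity_pct, 100)

  # missing predictions are an error
  expect_error(performance(pred[-1, ], truth), class = "aidhs_validation_error")
})

test_that("confusion-matrix decomposition matches the direct computation", {
  set.seed(71)
  truth <- mk_truth(30, 30, 30, 30)
  pred <- tibble::tibble(
    subject_id = truth$subject_id,
    detection = sample(c("HS", "noHS"), 120, TRUE),
    lateralization = sample(c("left", "right"), 120, TRUE))
  pf <- performance(pred, truth)
  pat <- truth$group == "patient_HS"
  tp <- sum(pred$detection[pat] == "HS")
  tn <- sum(pred$detection[!pat] == "noHS")
  expect_equal(pf$overall$detection_pct, 100 * tp / sum(pat))
  expect_equal(pf$overall$specificity_pct, 100 * tn / sum(!pat))
  # n-weighted stratum sensitivities aggregate to the overall sensitivity
  side <- truth$lateralization[pat]
  det <- pf$per_subject$detection_correct[pat]
  agg <- sum(vapply(c("left", "right"), function(s) {
    sum(det[side == s])
  }, numeric(1))) / sum(pat)
  expect_equal(pf$overall$detection_pct, 100 * agg)
})

test_that("correctness regression recovers injected factor effects", {
  set.seed(72)
  n <- 500
  f1 <- sample(c("a", "b"), n, TRUE)
  f2 <- sample(c("x", "y"), n, TRUE)
  # factor f1=b has odds ratio 3 for being correct
  eta <- 0.3 + log(3) * (f1 == "b")
  correct <- rbinom(n, 1, plogis(eta)) == 1
  reg <- stratified_regression(correct, data.frame(f1 = f1, f2 = f2))
  b1 <- reg[reg$term == "f1b", ]
  expect_lt(abs(b1$beta - log(3)), 2 * 0.25)
  expect_lt(b1$p_value, 0.05)
  # null factor not significant
  expect_gt(reg$p_value[reg$term == "f2y"], 0.01)
  # constant outcome: flagged degenerate result, no estimates fabricated
  reg0 <- stratified_regression(rep(TRUE, n), data.frame(f1 = f1))
  expect_equal(nrow(reg0), 0)
  # single-level factor rejected
  expect_error(stratified_regression(correct, data.frame(f1 = rep("a", n))),
               class = "aidhs_validation_error")
})

test_that("separation is reported, not hidden", {
  set.seed(73)
  n <- 80
  f1 <- rep(c("a", "b"), each = n / 2)
  correct <- c(rbinom(n / 2, 1, 0.7), rep(1, n / 2)) == 1  # b always correct
  reg <- stratified_regression(correct, data.frame(f1 = f1))
  row <- reg[reg$term == "f1b", ]
  expect_gt(abs(row$beta), 10)
  expect_gt(row$p_value, 0.9)
  expect_match(row$note, "separation")
})

test_that("group asymmetry tests gate on normality and correct with Holm", {
  fc <- feature_cohort(n_per_group = 34, sites = c("A", "B"), seed = 74)
  asym <- compute_asymmetry(skip_combat(fc$features))
  st <- fit_control_stats(asym, fc$demographics)
  z <- normalize_asymmetry(asym, st)
  tt <- asymmetry_group_tests(z, fc$demographics, seed = 7)
  expect_equal(nrow(tt), 15)   # 5 features x 3 pairs
  expect_true(all(tt$test %in% c("welch_t", "mann_whitney")))
  # Holm never decreases a p-value
  expect_true(all(tt$p_holm >= tt$p_raw - 1e-15))
  # patients differ from both control groups on every feature (2 SD-scale shifts)
  pat_rows <- tt[tt$comparison %in% c("patient_vs_healthy", "patient_vs_disease"), ]
  expect_true(all(pat_rows$p_holm < 0.05))
  # healthy vs disease: no injected difference; typical run has no rejections
  hd <- tt[tt$comparison == "healthy_vs_disease", ]
  expect_true(all(hd$p_holm > 0.05))
  # seeded hemisphere draw makes the table reproducible
  tt2 <- asymmetry_group_tests(z, fc$demographics, seed = 7)
  expect_equal(tt, tt2)
})

test_that("null asymmetries yield no rejections", {
  fc <- feature_cohort(n_per_group = 34, sites = c("A", "B"), seed = 75,
                       hs_multiplier = c(volume = 1, thickness = 1,
                                         gyrification = 1, curv_mean = 1,
                                         curv_intrinsic = 1))
  asym <- compute_asymmetry(skip_combat(fc$features))
  z <- normalize_asymmetry(asym, fit_control_stats(asym, fc$demographics))
  tt <- asymmetry_group_tests(z, fc$demographics, seed = 8)
  expect_true(all(tt$p_holm > 0.05))
  expect_error(asymmetry_group_tests(z[1:4, ], fc$demographics[1:4, ], seed = 1),
               class = "aidhs_validation_error")
})

test_that("the chi-square statistic matches closed forms", {
  # perfectly diagonal 2x2: chi-square = n, df = 1
  res <- contingency_chisq(rbind(c(10, 0), c(0, 10)))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)
  # proportional table: statistic 0
  res0 <- contingency_chisq(rbind(c(10, 20), c(30, 60)))
  expect_equal(res0$statistic, 0)
  expect_error(contingency_chisq(rbind(c(0, 0), c(3, 4))),
               class = "aidhs_validation_error")
})

test_that("stratified breakdown covers the recorded factors", {
  co <- small_cohort()
  m <- small_model()
  bd <- performance_breakdown(m$loso_predictions, co$demographics)
  expect_true(all(c("age_group", "sex") %in% bd$strata$factor))
  pat_n <- sum(co$demographics$group == "patient_HS")
  age_rows <- bd$strata[bd$strata$factor == "age_group", ]
  expect_equal(sum(age_rows$n), pat_n)   # strata partition the patients
  expect_true(all(bd$strata$detection_pct >= 0 & bd$strata$detection_pct <= 100))
})
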