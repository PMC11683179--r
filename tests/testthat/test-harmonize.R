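test_that("harmonization matches the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  fc <- feature_cohort(n_per_group = 15, sites = c("A", "B"), site_shift = 1,
                       seed = 11)
  fit <- fit_combat(fc$features, fc$demographics, min_site_n = 20)
  Y <- aidhs:::features_to_wide(fc$features)
  demo <- fc$demographics[match(rownames(Y), fc$demographics$subject_id), ]
  mod <- stats::model.matrix(~ age_years + factor(sex) + factor(group),
                             data = demo)
  ref <- t(suppressMessages(sva::ComBat(dat = t(Y), batch = demo$site_id,
                                        mod = mod)))
  mine <- aidhs:::features_to_wide(fit$harmonized)
  expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-5)
})

test_that("an injected additive site shift is removed", {
  fc <- feature_cohort(n_per_group = 50, sites = c("A", "B"), site_shift = 1,
                       seed = 12)   # 200 per site, shift = 1 within-site SD
  demo <- fc$demographics
  gap <- function(feats) {
    w <- aidhs:::features_to_wide(feats)
    s <- demo$site_id[match(rownames(w), demo$subject_id)]
    abs(mean(w[s == "A", "volume_left"]) - mean(w[s == "B", "volume_left"]))
  }
  pre <- gap(fc$features)
  fit <- fit_combat(fc$features, demo)
  post <- gap(fit$harmonized)
  expect_lt(post, 0.05 * pre)
})

test_that("null batch labels leave the data essentially unchanged", {
  fc <- feature_cohort(n_per_group = 40, sites = c("A", "B"), site_shift = 0,
                       seed = 13)
  fit <- fit_combat(fc$features, fc$demographics)
  pre <- aidhs:::features_to_wide(fc$features)
  post <- aidhs:::features_to_wide(fit$harmonized)[rownames(pre), ]
  # no spurious adjustment beyond EB shrinkage noise: relative change small
  expect_lt(max(abs(post - pre) / (abs(pre))), 0.05)
})

test_that("covariate effects survive harmonization", {
  # pure shift + common age slope (no HS effects, so the slope estimate is
  # a clean parameter-recovery problem)
  fc <- feature_cohort(n_per_group = 50, sites = c("A", "B"), site_shift = 1,
                       age_slope_volume = 10, seed = 14,
                       hs_multiplier = c(volume = 1, thickness = 1,
                                         gyrification = 1, curv_mean = 1,
                                         curv_intrinsic = 1))
  fit <- fit_combat(fc$features, fc$demographics)
  h <- dplyr::inner_join(fit$harmonized,
                         fc$demographics[, c("subject_id", "age_years")],
                         by = "subject_id")
  slope <- coef(lm(volume ~ age_years, data = h))[["age_years"]]
  expect_lt(abs(slope - 10) / 10, 0.10)
})

test_that("harmonization reduces the between-site variance component", {
  fc <- feature_cohort(n_per_group = 40, sites = c("A", "B", "C"),
                       site_shift = 1, seed = 15)
  demo <- fc$demographics
  site_ss <- function(feats) {
    w <- aidhs:::features_to_wide(feats)
    d <- demo[match(rownames(w), demo$subject_id), ]
    s <- factor(d$site_id)
    # site R^2 on residuals after biological covariates, summed over columns
    sum(vapply(colnames(w), function(cl) {
      r <- resid(lm(w[, cl] ~ d$age_years + d$sex + d$group))
      summary(lm(r ~ s))$r.squared
    }, numeric(1)))
  }
  expect_lt(site_ss(fit_combat(fc$features, demo)$harmonized),
            site_ss(fc$features))
})

test_that("model application is deterministic and guards its inputs", {
  fc <- feature_cohort(n_per_group = 20, sites = c("A", "B"), site_shift = 0.5,
                       seed = 16)
  fit <- fit_combat(fc$features, fc$demographics)
  # training rows reproduce stored harmonized values exactly
  re <- apply_combat(fit$model, fc$features, fc$demographics)
  expect_equal(aidhs:::features_to_wide(re),
               aidhs:::features_to_wide(fit$harmonized))
  # unseen site errors by default, passes through with a warning on request
  demo_new <- fc$demographics[1:10, ]
  demo_new$site_id <- "Z"
  demo_new$subject_id <- paste0("z", 1:10)
  feat_new <- fc$features[fc$features$subject_id %in% fc$demographics$subject_id[1:10], ]
  feat_new$subject_id <- rep(paste0("z", 1:10), each = 2)
  expect_error(apply_combat(fit$model, feat_new, demo_new),
               class = "aidhs_parameter_error")
  expect_warning(out <- apply_combat(fit$model, feat_new, demo_new,
                                     new_sites = "passthrough"))
  cmp <- dplyr::inner_join(out, feat_new, by = c("subject_id", "hemisphere"))
  expect_equal(unname(cmp$volume.x), cmp$volume.y)
  # zero-variance feature is named
  feat_const <- fc$features
  feat_const$thickness <- 1.5
  expect_error(apply_combat(fit$model, feat_const, fc$demographics),
               "thickness", class = "aidhs_validation_error")
})

test_that("single site or undersized sites are rejected with guidance", {
  fc <- feature_cohort(n_per_group = 20, sites = "A", seed = 17)
  expect_error(fit_combat(fc$features, fc$demographics),
               "harmonize = FALSE", class = "aidhs_parameter_error")
  fc2 <- feature_cohort(n_per_group = 4, sites = c("A", "B"), seed = 18)
  expect_error(fit_combat(fc2$features, fc2$demographics),
               "minimum", class = "aidhs_parameter_error")
})

test_that("asymmetry index follows the two-point formula and its algebra", {
  mk <- function(l, r) {
    tibble::tibble(subject_id = "s", hemisphere = c("left", "right"),
                   volume = c(l, r), thickness = c(l, r),
                   gyrification = c(l, r), curv_mean = c(l, r),
                   curv_intrinsic = c(l, r), stage = "harmonized")
  }
  expect_equal(compute_asymmetry(mk(3, 1))$volume, 1.0)
  expect_equal(compute_asymmetry(mk(1, 3))$volume, -1.0)
  expect_equal(compute_asymmetry(mk(2.4, 2.4))$volume, 0)
  expect_error(compute_asymmetry(mk(1, -1)), class = "aidhs_validation_error")

  # antisymmetry and boundedness over random positive pairs
  set.seed(19)
  for (k in 1:200) {
    l <- runif(1, 0.01, 100); r <- runif(1, 0.01, 100)
    a <- compute_asymmetry(mk(l, r))$volume
    b <- compute_asymmetry(mk(r, l))$volume
    expect_equal(a, -b)
    expect_true(a > -2 && a < 2)
  }
})

test_that("control statistics are estimated from healthy controls only", {
  set.seed(20)
  n <- 60
  asym <- tibble::tibble(subject_id = sprintf("c%02d", 1:n))
  for (f in aidhs_features()) asym[[f]] <- rnorm(n, 0.01, 0.05)
  demo <- tibble::tibble(subject_id = asym$subject_id,
                         group = rep(c("healthy_control", "disease_control",
                                       "patient_HS"), each = n / 3))
  st <- fit_control_stats(asym, demo)
  hc <- asym[1:20, ]
  expect_equal(st$mean[["volume"]], mean(hc$volume))
  expect_equal(st$sd[["volume"]], sd(hc$volume))
  # patient/disease rows do not influence the stats
  asym2 <- asym
  asym2$volume[21:60] <- 99
  st2 <- fit_control_stats(asym2, demo)
  expect_equal(st2$mean, st$mean)
  # zero SD errors
  asym3 <- asym
  asym3$volume[1:20] <- 0.42
  expect_error(fit_control_stats(asym3, demo), class = "aidhs_validation_error")
})

test_that("normalization is exact z-scoring against the reference controls", {
  set.seed(21)
  n <- 40
  asym <- tibble::tibble(subject_id = sprintf("h%02d", 1:n))
  for (f in aidhs_features()) asym[[f]] <- rnorm(n, 0.02, 0.04)
  demo <- tibble::tibble(subject_id = asym$subject_id,
                         group = "healthy_control")
  st <- fit_control_stats(asym, demo)
  z <- normalize_asymmetry(asym, st)
  for (f in aidhs_features()) {
    expect_equal(mean(z[[f]]), 0)
    expect_equal(sd(z[[f]]), 1)
  }
  # closed-form points
  a1 <- asym[1, ]
  a1$volume <- st$mean[["volume"]]
  expect_equal(normalize_asymmetry(a1, st)$volume, 0)
  a1$volume <- st$mean[["volume"]] + 2 * st$sd[["volume"]]
  expect_equal(normalize_asymmetry(a1, st)$volume, 2)
})
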