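sim_xy <- function(n, sep = 3, seed = 1, noise = 1) {
  set.seed(seed)
  y <- sample(aidhs:::aidhs_classes(), n, TRUE, prob = c(0.25, 0.25, 0.5))
  mu <- rbind(left_HS = c(-sep, -sep, -sep, sep, sep),
              right_HS = c(sep, sep, sep, -sep, -sep),
              no_HS = rep(0, 5))
  X <- mu[y, ] + matrix(rnorm(n * 5, 0, noise), n)
  dimnames(X) <- list(NULL, aidhs_features())
  list(X = X, y = y)
}

test_that("separable classes are fit to near-perfect training accuracy", {
  d <- sim_xy(300, sep = 4, seed = 51, noise = 0.5)
  fit <- fit_classifier(d$X, d$y)
  sc <- predict_scores(fit, d$X)
  pred <- aidhs:::aidhs_classes()[max.col(as.matrix(sc))]
  expect_gte(mean(pred == d$y), 0.99)
})

test_that("the fit matches an independent multinomial implementation", {
  skip_if_not_installed("nnet")
  d <- sim_xy(300, sep = 1, seed = 52, noise = 1.5)  # overlapping classes
  fit <- fit_classifier(d$X, d$y, lambda = 0)
  w <- nrow(d$X) / (3 * table(d$y)[d$y])
  df <- data.frame(y = factor(d$y, levels = aidhs:::aidhs_classes()), d$X)
  ref <- nnet::multinom(y ~ ., data = df, weights = as.numeric(w), decay = 0,
                        maxit = 500, trace = FALSE, reltol = 1e-12)
  p_ref <- predict(ref, df, type = "probs")
  p_mine <- as.matrix(predict_scores(fit, d$X))
  expect_lt(max(abs(p_mine - p_ref)), 1e-3)
})

test_that("label permutation drives cross-validated accuracy to chance", {
  d <- sim_xy(240, sep = 3, seed = 53)
  set.seed(54)
  y_perm <- sample(d$y)
  # 4-fold CV under permuted labels
  fold <- rep(1:4, length.out = 240)
  acc <- vapply(1:4, function(k) {
    fit <- fit_classifier(d$X[fold != k, ], y_perm[fold != k])
    sc <- predict_scores(fit, d$X[fold == k, , drop = FALSE])
    mean(aidhs:::aidhs_classes()[max.col(as.matrix(sc))] == y_perm[fold == k])
  }, numeric(1))
  expect_lt(mean(acc), 0.45)   # chance is 1/3 for balanced scoring
})

test_that("balanced weights make the fit invariant to majority duplication", {
  d <- sim_xy(300, sep = 1.5, seed = 55)
  fit <- fit_classifier(d$X, d$y, lambda = 0)
  dup <- d$y == "no_HS"
  fit2 <- fit_classifier(rbind(d$X, d$X[dup, ]), c(d$y, d$y[dup]), lambda = 0)
  expect_equal(fit2$coef, fit$coef, tolerance = 1e-5)
})

test_that("classifier input is validated", {
  d <- sim_xy(60, seed = 56)
  expect_error(fit_classifier(d$X[d$y != "left_HS", ], d$y[d$y != "left_HS"]),
               "left_HS", class = "aidhs_validation_error")
  Xb <- d$X; Xb[1, 1] <- NA
  expect_error(fit_classifier(Xb, d$y), class = "aidhs_validation_error")
  fit <- fit_classifier(d$X, d$y)
  expect_error(predict_scores(fit, d$X[, 1:3]), class = "aidhs_format_error")
})

test_that("scores are softmax probabilities and decisions match argmax", {
  d <- sim_xy(200, seed = 57)
  fit <- fit_classifier(d$X, d$y)
  sc <- predict_scores(fit, matrix(rnorm(5000), ncol = 5,
                                   dimnames = list(NULL, aidhs_features())))
  expect_equal(rowSums(as.matrix(sc)), rep(1, 1000))
  expect_true(all(as.matrix(sc) >= 0))

  # randomized brute-force oracle over probability triplets
  set.seed(58)
  p <- matrix(stats::rexp(3 * 10000), ncol = 3)
  p <- p / rowSums(p)
  scores <- tibble::tibble(s_lhs = p[, 1], s_rhs = p[, 2], s_nohs = p[, 3])
  dec <- decide(scores)
  oracle_det <- ifelse(apply(p, 1, which.max) == 3, "noHS", "HS")
  # spec tie rule: noHS wins ties against the best lateralized score
  oracle_det[p[, 3] >= pmax(p[, 1], p[, 2])] <- "noHS"
  oracle_lat <- ifelse(p[, 1] >= p[, 2], "left", "right")
  expect_equal(dec$detection, oracle_det)
  expect_equal(dec$lateralization, oracle_lat)

  # documented tie handling
  expect_warning(tie <- decide(tibble::tibble(s_lhs = 0.3, s_rhs = 0.3,
                                              s_nohs = 0.4)))
  expect_equal(tie$detection, "noHS")
  expect_equal(tie$lateralization, "left")
  expect_equal(decide(tibble::tibble(s_lhs = 0.2, s_rhs = 0.1, s_nohs = 0.7)),
               tibble::tibble(detection = "noHS", lateralization = "left"))
  expect_equal(decide(tibble::tibble(s_lhs = 0.6, s_rhs = 0.3, s_nohs = 0.1)),
               tibble::tibble(detection = "HS", lateralization = "left"))
})

test_that("the sign convention maps strong left-referenced deficits to left HS", {
  fc <- feature_cohort(n_per_group = 30, sites = c("A", "B"), seed = 59)
  res <- loso_cv(fc$features, fc$demographics, harmonize = FALSE)
  fold <- res$folds[[1]]
  # strongly negative volume/thickness/gyrification asymmetries: left HS
  x_left <- matrix(c(-6, -6, -6, 6, 6), 1,
                   dimnames = list("q", aidhs_features()))
  sc <- predict_scores(fold$classifier, x_left)
  expect_gt(sc$s_lhs, pmax(sc$s_rhs, sc$s_nohs))
  # symmetric subject: no HS
  sc0 <- predict_scores(fold$classifier,
                        matrix(0, 1, 5, dimnames = list("q", aidhs_features())))
  expect_gt(sc0$s_nohs, pmax(sc0$s_lhs, sc0$s_rhs))
})

test_that("mirroring the cohort mirrors the decisions", {
  fc <- feature_cohort(n_per_group = 25, sites = c("A", "B"), seed = 60)
  res <- loso_cv(fc$features, fc$demographics, harmonize = FALSE)
  # swap hemispheres in the raw features: asymmetries negate, labels mirror
  fc_m <- fc
  fc_m$features$hemisphere <- ifelse(fc$features$hemisphere == "left",
                                     "right", "left")
  fc_m$demographics$lateralization <- c(left = "right", right = "left",
                                        none = "none")[fc$demographics$lateralization]
  res_m <- loso_cv(fc_m$features, fc_m$demographics, harmonize = FALSE)
  j <- match(res$predictions$subject_id, res_m$predictions$subject_id)
  expect_equal(res_m$predictions$s_lhs[j], res$predictions$s_rhs,
               tolerance = 1e-6)
  expect_equal(res_m$predictions$detection[j], res$predictions$detection)
})

test_that("leave-one-site-out honors the partition and leaks nothing", {
  fc <- feature_cohort(n_per_group = 25, sites = c("A", "B", "C", "D"),
                       seed = 61)
  res <- loso_cv(fc$features, fc$demographics, min_site_n = 20)
  expect_length(res$folds, 4)
  for (s in names(res$folds)) {
    expect_false(s %in% res$folds[[s]]$train_sites)
    expect_setequal(res$folds[[s]]$train_sites, setdiff(c("A", "B", "C", "D"), s))
  }
  # each subject exactly one out-of-fold prediction
  expect_setequal(res$predictions$subject_id, fc$demographics$subject_id)
  expect_false(anyDuplicated(res$predictions$subject_id) > 0)

  # leakage audit: fitting a fold with the held-out rows deleted up front
  # yields a bit-identical fold model
  keep <- fc$demographics$site_id != "A"
  demo_del <- fc$demographics[keep, ]
  feat_del <- fc$features[fc$features$subject_id %in% demo_del$subject_id, ]
  fold_full <- aidhs:::fit_fold(fc$features, fc$demographics,
                                train_sites = c("B", "C", "D"), test_site = "A",
                                min_site_n = 20)
  fold_del <- aidhs:::fit_fold(feat_del, demo_del,
                               train_sites = c("B", "C", "D"), test_site = "A",
                               min_site_n = 20)
  expect_identical(fold_full$classifier$coef, fold_del$classifier$coef)
  expect_identical(fold_full$combat$gamma_star, fold_del$combat$gamma_star)
  expect_identical(fold_full$control_stats$mean, fold_del$control_stats$mean)
})

test_that("ensembling averages fold probabilities", {
  fc <- feature_cohort(n_per_group = 25, sites = c("A", "B"), seed = 62)
  res <- loso_cv(fc$features, fc$demographics, harmonize = FALSE)
  one <- res$folds[[1]]
  # identical folds predict identically to a single fold
  ens <- ensemble_predict(list(one, one, one), fc$features, fc$demographics)
  single <- predict_scores(one$classifier,
                           aidhs:::fold_features(one, fc$features, fc$demographics))
  j <- match(ens$subject_id, single$subject_id)
  expect_equal(ens$s_lhs, single$s_lhs[j], tolerance = 1e-12)
  expect_equal(rowSums(as.matrix(ens[, c("s_lhs", "s_rhs", "s_nohs")])),
               rep(1, nrow(ens)))
  expect_error(ensemble_predict(list(), fc$features, fc$demographics),
               class = "aidhs_parameter_error")

  # the combination rule is the arithmetic mean of fold probabilities
  ens2 <- ensemble_predict(res$folds, fc$features, fc$demographics)
  per_fold <- lapply(res$folds, function(fd) {
    sc <- predict_scores(fd$classifier,
                         aidhs:::fold_features(fd, fc$features, fc$demographics))
    m <- as.matrix(sc[, c("s_lhs", "s_rhs", "s_nohs")])
    rownames(m) <- sc$subject_id
    m
  })
  manual <- Reduce(`+`, lapply(per_fold, function(m) m[ens2$subject_id, ])) /
    length(per_fold)
  manual <- manual / rowSums(manual)
  expect_equal(as.matrix(ens2[, c("s_lhs", "s_rhs", "s_nohs")]), manual,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("two opposed fold votes average to a split score", {
  # construct two degenerate folds around hand-made classifiers
  mk_fold <- function(coefs) {
    clf <- structure(list(coef = coefs, features = aidhs_features(),
                          lambda = 1, converged = TRUE, n = 10,
                          classes = aidhs:::aidhs_classes()),
                     class = "aidhs_multinom")
    structure(list(classifier = clf, combat = NULL, control_stats = NULL,
                   train_sites = "A", test_site = "B", harmonize = FALSE,
                   feature_set = aidhs_features(), input = "raw",
                   new_sites = "estimate"), class = "aidhs_fold")
  }
  base <- matrix(0, 3, 6, dimnames = list(aidhs:::aidhs_classes(),
                                          c("(Intercept)", aidhs_features())))
  c1 <- base; c1["left_HS", 1] <- 50    # fold 1 votes (1, 0, 0)
  c2 <- base; c2["right_HS", 1] <- 50   # fold 2 votes (0, 1, 0)
  x <- matrix(0, 1, 5, dimnames = list("s1", aidhs_features()))
  cols <- c("s_lhs", "s_rhs", "s_nohs")
  p1 <- predict_scores(mk_fold(c1)$classifier, x)
  p2 <- predict_scores(mk_fold(c2)$classifier, x)
  avg <- (as.matrix(p1[, cols]) + as.matrix(p2[, cols])) / 2
  expect_equal(as.numeric(avg), c(0.5, 0.5, 0), tolerance = 1e-15)
})

test_that("abnormality thresholds sit at the midpoint of separated groups", {
  set.seed(63)
  n <- 200
  demo <- tibble::tibble(
    subject_id = sprintf("t%03d", 1:(3 * n)),
    group = rep(c("patient_HS", "patient_HS", "healthy_control"), each = n),
    lateralization = rep(c("left", "right", "none"), each = n))
  asym <- tibble::tibble(subject_id = demo$subject_id)
  for (f in aidhs_features()) {
    asym[[f]] <- c(rnorm(n, -3, 1), rnorm(n, 3, 1), rnorm(n, 0, 1))
  }
  thr <- fit_abnormality_thresholds(asym, demo)
  left <- thr[thr$side == "left", ]
  right <- thr[thr$side == "right", ]
  # equal-variance balanced Gaussians: boundary near the midpoint
  expect_true(all(abs(left$threshold - (-1.5)) < 0.5))
  expect_true(all(abs(right$threshold - 1.5) < 0.5))
  expect_true(all(left$threshold < 0 & right$threshold > 0))

  # boundary equivalence: the threshold reproduces the 0.5 rule of the glm
  f <- "volume"
  sel <- demo$lateralization != "right"
  y <- as.numeric(demo$lateralization[sel] == "left")
  x <- asym[[f]][sel]
  fitg <- glm(y ~ x, family = binomial())
  t_row <- left[left$feature == f, ]
  pred_thr <- if (t_row$slope > 0) x > t_row$threshold else x < t_row$threshold
  expect_equal(pred_thr, unname(predict(fitg, type = "response") > 0.5))
})

test_that("the volume baseline uses the shared partition and volume only", {
  fc <- feature_cohort(n_per_group = 25, sites = c("A", "B"), seed = 64)
  base <- fit_volume_baseline(fc$features, fc$demographics, preprocessed = TRUE,
                              min_site_n = 20)
  expect_equal(base$folds[[1]]$feature_set, "volume")
  expect_setequal(base$predictions$subject_id, fc$demographics$subject_id)
  raw <- fit_volume_baseline(fc$features, fc$demographics, preprocessed = FALSE)
  expect_equal(raw$folds[[1]]$input, "raw")
  perf_raw <- performance(raw$predictions, fc$demographics)$overall

  # volume carries the dominant signal here: baseline close to full model
  full <- loso_cv(fc$features, fc$demographics, min_site_n = 20)
  perf_full <- performance(full$predictions, fc$demographics)$overall
  perf_base <- performance(base$predictions, fc$demographics)$overall
  expect_gt(perf_base$detection_pct, 90)
  expect_gt(perf_full$detection_pct, 90)

  # signal in curvature only: the full model outperforms the baseline
  fc2 <- feature_cohort(n_per_group = 25, sites = c("A", "B"), seed = 65,
                        hs_multiplier = c(volume = 1, thickness = 1,
                                          gyrification = 1, curv_mean = 1.3,
                                          curv_intrinsic = 1.3))
  base2 <- fit_volume_baseline(fc2$features, fc2$demographics)
  full2 <- loso_cv(fc2$features, fc2$demographics)
  p_base2 <- performance(base2$predictions, fc2$demographics)$overall
  p_full2 <- performance(full2$predictions, fc2$demographics)$overall
  expect_gt(p_full2$detection_pct, p_base2$detection_pct + 10)
})
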