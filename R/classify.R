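aidhs_classes <- function() c("left_HS", "right_HS", "no_HS")

#' Derive classifier labels from demographics
#'
#' Unilateral HS patients map to `left_HS` / `right_HS`; healthy and disease
#' controls both map to `no_HS`. Bilateral HS patients get `NA`: they are
#' never used for training and pass through prediction and reporting only.
#'
#' @param demographics demographics tibble.
#' @return character vector of labels aligned with the rows.
#' @export
make_labels <- function(demographics) {
  lab <- rep("no_HS", nrow(demographics))
  pat <- demographics$group == "patient_HS"
  lab[pat & demographics$lateralization == "left"] <- "left_HS"
  lab[pat & demographics$lateralization == "right"] <- "right_HS"
  lab[pat & demographics$lateralization == "bilateral"] <- NA_character_
  lab
}

multinom_nll <- function(par, X1, Yind, w, lambda, K, p1) {
  Theta <- matrix(par, nrow = K)           # K x (p + 1), intercept first
  eta <- X1 %*% t(Theta)
  eta <- eta - apply(eta, 1, max)
  P <- exp(eta)
  P <- P / rowSums(P)
  nll <- -sum(w * log(P[Yind] + 1e-300))
  pen <- 0.5 * lambda * sum(Theta[, -1]^2)
  nll + pen
}

multinom_grad <- function(par, X1, Yind, w, lambda, K, p1) {
  Theta <- matrix(par, nrow = K)
  eta <- X1 %*% t(Theta)
  eta <- eta - apply(eta, 1, max)
  P <- exp(eta)
  P <- P / rowSums(P)
  R <- P
  R[Yind] <- R[Yind] - 1
  G <- t(R * w) %*% X1                      # K x (p + 1)
  G[, -1] <- G[, -1] + lambda * Theta[, -1]
  as.numeric(G)
}

#' Fit the three-class asymmetry classifier
#'
#' Multinomial logistic regression on the normalized asymmetry features with
#' balanced class weights (`w_i = n / (K * n_class(i))`) to counter label
#' imbalance, and weak L2 regularization of the non-intercept coefficients.
#' The convex objective is minimized with L-BFGS from a zero start, so the
#' fit is fully deterministic given the data.
#'
#' @param x numeric matrix (subjects x features).
#' @param labels character/factor labels among `left_HS`, `right_HS`, `no_HS`.
#' @param lambda L2 penalty strength (inverse regularization strength 1 /
#'   lambda; default 1, set 0 to disable).
#' @param maxit maximum L-BFGS iterations.
#' @return object of class `aidhs_multinom` with the coefficient matrix
#'   (classes x c(intercept, features)).
#' @export
fit_classifier <- function(x, labels, lambda = 1, maxit = 1000) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) {
    abort_aidhs("non-finite feature values in classifier input", "aidhs_validation_error")
  }
  labels <- as.character(labels)
  missing_cls <- setdiff(aidhs_classes(), unique(labels))
  if (length(missing_cls) > 0) {
    abort_aidhs(sprintf("training data lacks class(es): %s",
                        paste(missing_cls, collapse = ", ")),
                "aidhs_validation_error")
  }
  K <- 3L
  n <- nrow(x)
  y <- match(labels, aidhs_classes())
  n_k <- tabulate(y, nbins = K)
  w <- n / (K * n_k[y])                     # balanced class weights
  X1 <- cbind(1, x)
  Yind <- cbind(seq_len(n), y)
  p1 <- ncol(X1)
  opt <- optim(rep(0, K * p1), fn = multinom_nll, gr = multinom_grad,
               X1 = X1, Yind = Yind, w = w, lambda = lambda, K = K, p1 = p1,
               method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e7))
  Theta <- matrix(opt$par, nrow = K,
                  dimnames = list(aidhs_classes(), c("(Intercept)", colnames(x))))
  structure(list(coef = Theta, features = colnames(x), lambda = lambda,
                 converged = opt$convergence == 0, n = n, classes = aidhs_classes()),
            class = "aidhs_multinom")
}

#' @export
print.aidhs_multinom <- function(x, ...) {
  cat(sprintf("<aidhs_multinom> 3 classes, features: %s\n",
              paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Class scores for subjects
#'
#' Softmax probabilities `[s_lhs, s_rhs, s_nohs]`; each row sums to 1.
#'
#' @param model an `aidhs_multinom` from [fit_classifier()].
#' @param x feature matrix with the model's feature columns.
#' @return tibble `s_lhs`, `s_rhs`, `s_nohs` (plus `subject_id` when `x` has
#'   row names).
#' @export
predict_scores <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$features)) {
    abort_aidhs(sprintf("expected %d features, got %d",
                        length(model$features), ncol(x)),
                "aidhs_format_error")
  }
  eta <- cbind(1, x) %*% t(model$coef)
  eta <- eta - apply(eta, 1, max)
  P <- exp(eta)
  P <- P / rowSums(P)
  out <- tibble::tibble(s_lhs = unname(P[, "left_HS"]),
                        s_rhs = unname(P[, "right_HS"]),
                        s_nohs = unname(P[, "no_HS"]))
  if (!is.null(rownames(x))) out <- dplyr::bind_cols(
    tibble::tibble(subject_id = rownames(x)), out)
  out
}

#' Detection and lateralization decisions
#'
#' Detection labels a subject `HS` when the best lateralized score exceeds
#' the no-HS score (`noHS` when `s_nohs >= max(s_lhs, s_rhs)`; the tie goes
#' conservatively to `noHS`). Lateralization is `left` when
#' `s_lhs >= s_rhs` (ties go to `left` with a warning) and is defined for
#' every subject regardless of the detection outcome.
#'
#' @param scores tibble or matrix with columns `s_lhs`, `s_rhs`, `s_nohs`.
#' @return tibble `detection` (`HS`/`noHS`), `lateralization` (`left`/`right`).
#' @export
decide <- function(scores) {
  s_lhs <- scores[["s_lhs"]] %||% scores[, "s_lhs"]
  s_rhs <- scores[["s_rhs"]] %||% scores[, "s_rhs"]
  s_nohs <- scores[["s_nohs"]] %||% scores[, "s_nohs"]
  if (any(s_lhs == s_rhs)) {
    warning("tied lateralized scores; lateralization set to 'left'", call. = FALSE)
  }
  tibble::tibble(
    detection = ifelse(s_nohs >= pmax(s_lhs, s_rhs), "noHS", "HS"),
    lateralization = ifelse(s_lhs >= s_rhs, "left", "right")
  )
}

# Build the classifier input matrix for one fold's state.
fold_features <- function(fold, features, demographics) {
  if (fold$input == "raw") {
    wide <- features_to_wide(features)
    cols <- as.vector(outer(fold$feature_set, c("left", "right"), paste, sep = "_"))
    return(wide[, cols, drop = FALSE])
  }
  harm <- if (fold$harmonize) {
    apply_combat(fold$combat, features, demographics, new_sites = fold$new_sites)
  } else {
    skip_combat(features)
  }
  asym <- compute_asymmetry(harm)
  norm <- normalize_asymmetry(asym, fold$control_stats)
  m <- as.matrix(norm[, fold$feature_set, drop = FALSE])
  rownames(m) <- norm$subject_id
  m
}

fit_fold <- function(features, demographics, train_sites, test_site,
                     harmonize = TRUE, feature_set = aidhs_features(),
                     input = "asymmetry", min_site_n = 20, lambda = 1,
                     new_sites = "estimate") {
  demo_tr <- demographics[demographics$site_id %in% train_sites, ]
  labels <- make_labels(demo_tr)
  demo_tr <- demo_tr[!is.na(labels), ]      # bilateral HS never trains
  feat_tr <- features[features$subject_id %in% demo_tr$subject_id, ]
  if (sum(demo_tr$group == "healthy_control") < 2) {
    abort_aidhs(sprintf("training fold (test site %s) lacks healthy controls for normalization",
                        test_site), "aidhs_validation_error")
  }
  # a fold trained on a single site has no batch structure to model
  if (length(unique(demo_tr$site_id)) < 2) harmonize <- FALSE
  combat <- NULL
  control_stats <- NULL
  if (input == "asymmetry") {
    if (harmonize) {
      fit <- fit_combat(feat_tr, demo_tr, min_site_n = min_site_n)
      combat <- fit$model
      harm <- fit$harmonized
    } else {
      harm <- skip_combat(feat_tr)
    }
    asym <- compute_asymmetry(harm)
    control_stats <- fit_control_stats(asym, demo_tr)
    norm <- normalize_asymmetry(asym, control_stats)
    X <- as.matrix(norm[, feature_set, drop = FALSE])
    rownames(X) <- norm$subject_id
  } else {
    wide <- features_to_wide(feat_tr)
    cols <- as.vector(outer(feature_set, c("left", "right"), paste, sep = "_"))
    X <- wide[, cols, drop = FALSE]
  }
  y <- make_labels(demo_tr)[match(rownames(X), demo_tr$subject_id)]
  clf <- fit_classifier(X, y, lambda = lambda)
  structure(list(classifier = clf, combat = combat, control_stats = control_stats,
                 train_sites = sort(train_sites), test_site = test_site,
                 harmonize = harmonize, feature_set = feature_set,
                 input = input, new_sites = new_sites),
            class = "aidhs_fold")
}

#' Leave-one-site-out cross-validation
#'
#' Trains one fold model per site, each on the remaining sites only:
#' harmonization, control asymmetry statistics, and classifier coefficients
#' are all refit within the training fold so no held-out-site information
#' leaks in. The held-out site is then transformed with the fold's stored
#' state (its site location/scale estimated from its own rows when
#' harmonization is on) and scored, so every subject receives exactly one
#' out-of-fold prediction.
#'
#' @param features raw (stage `"raw"`) feature tibble for the full cohort.
#' @param demographics demographics tibble.
#' @param harmonize run the batch-harmonization step (`FALSE` = identity).
#' @param feature_set features used by the classifier (default all five).
#' @param input `"asymmetry"` (normalized asymmetries; the full pipeline) or
#'   `"raw"` (per-hemisphere raw columns; used by the volume baseline).
#' @param min_site_n minimum site size for harmonization.
#' @param lambda classifier L2 penalty.
#' @return list with `predictions` (tibble: `subject_id`, `site_id`,
#'   `s_lhs`, `s_rhs`, `s_nohs`, `detection`, `lateralization`, `fold`) and
#'   `folds` (list of fold models).
#' @export
loso_cv <- function(features, demographics, harmonize = TRUE,
                    feature_set = aidhs_features(), input = "asymmetry",
                    min_site_n = 20, lambda = 1) {
  sites <- sort(unique(demographics$site_id))
  if (length(sites) < 2) {
    abort_aidhs("leave-one-site-out requires at least 2 sites", "aidhs_parameter_error")
  }
  folds <- list()
  preds <- list()
  for (s in sites) {
    fold <- fit_fold(features, demographics,
                     train_sites = setdiff(sites, s), test_site = s,
                     harmonize = harmonize, feature_set = feature_set,
                     input = input, min_site_n = min_site_n, lambda = lambda)
    demo_te <- demographics[demographics$site_id == s, ]
    feat_te <- features[features$subject_id %in% demo_te$subject_id, ]
    Xte <- fold_features(fold, feat_te, demo_te)
    sc <- predict_scores(fold$classifier, Xte)
    if (is.null(sc[["subject_id"]])) sc$subject_id <- rownames(Xte)
    dec <- decide(sc)
    preds[[s]] <- dplyr::bind_cols(
      tibble::tibble(subject_id = sc$subject_id,
                     site_id = demo_te$site_id[match(sc$subject_id, demo_te$subject_id)]),
      sc[, c("s_lhs", "s_rhs", "s_nohs")], dec,
      tibble::tibble(fold = s))
    folds[[s]] <- fold
  }
  list(predictions = dplyr::bind_rows(preds), folds = folds)
}

#' Ensemble prediction over fold models
#'
#' Each fold transforms the new data with its own harmonization and
#' normalization state and scores it; the fold probability vectors are then
#' averaged arithmetically and renormalized.
#'
#' @param folds list of fold models (from [loso_cv()] or a model bundle).
#' @param features raw feature tibble for the subjects to score.
#' @param demographics matching demographics tibble.
#' @return tibble `subject_id`, `s_lhs`, `s_rhs`, `s_nohs`, `detection`,
#'   `lateralization`.
#' @export
ensemble_predict <- function(folds, features, demographics) {
  if (length(folds) == 0) {
    abort_aidhs("empty ensemble", "aidhs_parameter_error")
  }
  acc <- NULL
  ids <- NULL
  for (fold in folds) {
    X <- fold_features(fold, features, demographics)
    sc <- predict_scores(fold$classifier, X)
    m <- as.matrix(sc[, c("s_lhs", "s_rhs", "s_nohs")])
    if (is.null(acc)) {
      acc <- m
      ids <- rownames(X)
    } else {
      acc <- acc + m[match(ids, rownames(X)), , drop = FALSE]
    }
  }
  acc <- acc / length(folds)
  acc <- acc / rowSums(acc)
  sc <- tibble::tibble(subject_id = ids, s_lhs = acc[, 1], s_rhs = acc[, 2],
                       s_nohs = acc[, 3])
  dplyr::bind_cols(sc, decide(sc))
}

#' Per-feature abnormality thresholds
#'
#' For each feature and each side, a univariate logistic regression separates
#' patients of that side from all controls (healthy and disease) on the
#' normalized asymmetry axis; the threshold is the probability-0.5 decision
#' boundary `-intercept / slope`. Degenerate fits (no separation direction,
#' or complete separation) are flagged.
#'
#' @param norm_asym normalized asymmetry tibble.
#' @param demographics demographics tibble.
#' @return tibble `feature`, `side`, `threshold`, `slope`, `flagged`.
#' @export
fit_abnormality_thresholds <- function(norm_asym, demographics) {
  labels <- make_labels(demographics)[match(norm_asym$subject_id,
                                            demographics$subject_id)]
  out <- list()
  for (side in c("left", "right")) {
    cls <- paste0(side, "_HS")
    sel <- !is.na(labels) & (labels == cls | labels == "no_HS")
    y <- as.numeric(labels[sel] == cls)
    for (f in aidhs_features()) {
      x <- norm_asym[[f]][sel]
      flagged <- FALSE
      fit <- withCallingHandlers(
        glm(y ~ x, family = binomial()),
        warning = function(w) {
          flagged <<- TRUE
          invokeRestart("muffleWarning")
        }
      )
      b <- coef(fit)
      slope <- unname(b[2])
      thr <- if (is.na(slope) || abs(slope) < 1e-12) {
        flagged <- TRUE
        NA_real_
      } else {
        unname(-b[1] / slope)
      }
      out[[paste(side, f)]] <- tibble::tibble(
        feature = f, side = side, threshold = thr, slope = slope,
        flagged = flagged || !fit$converged
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Volume-only baseline classifier
#'
#' Same classifier configuration restricted to hippocampal volume, for
#' comparison runs: either raw left/right volumes (`preprocessed = FALSE`)
#' or the harmonized, normalized volume asymmetry (`preprocessed = TRUE`).
#' Honors the same leave-one-site-out partition contract.
#'
#' @inheritParams loso_cv
#' @param preprocessed apply harmonization + asymmetry normalization.
#' @return as [loso_cv()].
#' @export
fit_volume_baseline <- function(features, demographics, preprocessed = TRUE,
                                min_site_n = 20, lambda = 1) {
  loso_cv(features, demographics,
          harmonize = preprocessed,
          feature_set = "volume",
          input = if (preprocessed) "asymmetry" else "raw",
          min_site_n = min_site_n, lambda = lambda)
}
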