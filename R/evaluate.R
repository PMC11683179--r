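#' Detection/lateralization performance
#'
#' Detection sensitivity is the fraction of unilateral HS patients decided
#' `HS`; lateralization sensitivity is the fraction of unilateral HS patients
#' whose predicted side matches the true side (computed for all patients,
#' whether or not they were detected); specificity is the fraction of
#' controls (healthy and disease) decided `noHS`.
#'
#' @param predictions tibble with `subject_id`, `detection`,
#'   `lateralization` (e.g. from [loso_cv()]).
#' @param demographics demographics tibble with the truth.
#' @return list with `overall` (one-row tibble of percentages and counts)
#'   and `per_subject` (tibble with per-subject correctness flags).
#' @export
performance <- function(predictions, demographics) {
  demo <- demographics
  idx <- match(demo$subject_id, predictions$subject_id)
  if (anyNA(idx)) {
    abort_aidhs(sprintf("missing prediction for subject(s): %s",
                        paste(demo$subject_id[is.na(idx)], collapse = ", ")),
                "aidhs_validation_error")
  }
  pred <- predictions[idx, ]
  is_patient <- demo$group == "patient_HS" &
    demo$lateralization %in% c("left", "right")
  is_control <- demo$group %in% c("healthy_control", "disease_control")

  det_ok <- ifelse(is_patient, pred$detection == "HS",
                   ifelse(is_control, pred$detection == "noHS", NA))
  lat_ok <- ifelse(is_patient, pred$lateralization == demo$lateralization, NA)

  per_subject <- tibble::tibble(
    subject_id = demo$subject_id, group = demo$group,
    lateralization = demo$lateralization,
    detection = pred$detection, lateralization_pred = pred$lateralization,
    detection_correct = det_ok, lateralization_correct = lat_ok
  )
  overall <- tibble::tibble(
    n_patients = sum(is_patient), n_controls = sum(is_control),
    detection_pct = 100 * mean(det_ok[is_patient]),
    lateralization_pct = 100 * mean(lat_ok[is_patient]),
    specificity_pct = 100 * mean(det_ok[is_control])
  )
  list(overall = overall, per_subject = per_subject)
}

#' Multivariable logistic regression of classifier correctness on cohort
#' factors
#'
#' One model regresses a per-subject correctness indicator on the supplied
#' stratification factors jointly. Under complete separation the affected
#' coefficients are reported as fitted (typically extreme, with p near 1)
#' and flagged in `note` rather than being silently dropped.
#'
#' @param correct logical vector of per-subject correctness.
#' @param factors data frame of factor columns (reference level = first
#'   level of each factor).
#' @return tibble `term`, `beta`, `p_value`, `note`.
#' @export
stratified_regression <- function(correct, factors) {
  factors <- as.data.frame(factors)
  keep <- vapply(factors, function(f) length(unique(f[!is.na(f)])) >= 2, logical(1))
  if (!all(keep)) {
    abort_aidhs(sprintf("factor(s) with fewer than 2 levels: %s",
                        paste(names(factors)[!keep], collapse = ", ")),
                "aidhs_validation_error")
  }
  if (length(unique(correct[!is.na(correct)])) < 2) {
    return(tibble::tibble(term = character(), beta = numeric(),
                          p_value = numeric(),
                          note = "constant outcome: factor effects undefined"))
  }
  dat <- cbind(data.frame(.y = as.numeric(correct)), factors)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)[-1]
  tibble::tibble(
    term = terms,
    beta = sm[-1, "Estimate"],
    p_value = sm[-1, "Pr(>|z|)"],
    note = ifelse((separated | sm[-1, "Pr(>|z|)"] > 0.9) &
                    abs(sm[-1, "Estimate"]) > 10,
                  "separation: estimate unreliable", "")
  )
}

#' Group comparisons of normalized asymmetries
#'
#' Compares, per feature, the ipsilateral-referenced normalized asymmetries
#' of HS patients against healthy controls and disease controls (controls
#' contribute a randomly selected hemisphere, which for a left-referenced
#' asymmetry vector means a random sign). Each group pair uses a Welch
#' t-test when both groups pass the Shapiro-Wilk normality check (p >= 0.05)
#' and a Mann-Whitney test otherwise; p-values are Holm-corrected across all
#' feature x pair tests.
#'
#' @param norm_asym normalized (left-referenced) asymmetry tibble.
#' @param demographics demographics tibble.
#' @param seed seed for the random control-hemisphere draw.
#' @return tibble `feature`, `comparison`, `test`, `statistic`, `p_raw`,
#'   `p_holm`.
#' @export
asymmetry_group_tests <- function(norm_asym, demographics, seed = 1) {
  demo <- demographics[match(norm_asym$subject_id, demographics$subject_id), ]
  lab <- make_labels(demo)
  is_pat <- !is.na(lab) & lab %in% c("left_HS", "right_HS")
  is_hc <- demo$group == "healthy_control"
  is_dc <- demo$group == "disease_control"
  if (sum(is_pat) < 3 || sum(is_hc) < 3 || sum(is_dc) < 3) {
    abort_aidhs("each group needs at least 3 subjects", "aidhs_validation_error")
  }

  # ipsilateral referencing: right-HS patients flip sign; controls get a
  # seeded random hemisphere (sign)
  sign_vec <- rep(1, nrow(demo))
  sign_vec[lab %in% "right_HS"] <- -1
  n_ctrl <- sum(is_hc | is_dc)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  sign_vec[is_hc | is_dc] <- sample(c(-1, 1), n_ctrl, replace = TRUE)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  pairs <- list(
    patient_vs_healthy = list(is_pat, is_hc),
    patient_vs_disease = list(is_pat, is_dc),
    healthy_vs_disease = list(is_hc, is_dc)
  )
  rows <- list()
  for (f in aidhs_features()) {
    v <- norm_asym[[f]] * sign_vec
    for (nm in names(pairs)) {
      a <- v[pairs[[nm]][[1]]]
      b <- v[pairs[[nm]][[2]]]
      normal <- shapiro.test(a)$p.value >= 0.05 && shapiro.test(b)$p.value >= 0.05
      tst <- if (normal) {
        t <- t.test(a, b)
        list(test = "welch_t", statistic = unname(t$statistic), p = t$p.value)
      } else {
        t <- suppressWarnings(wilcox.test(a, b))
        list(test = "mann_whitney", statistic = unname(t$statistic), p = t$p.value)
      }
      rows[[paste(f, nm)]] <- tibble::tibble(
        feature = f, comparison = nm, test = tst$test,
        statistic = tst$statistic, p_raw = tst$p)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_holm <- p.adjust(out$p_raw, method = "holm")
  out
}

#' Pearson chi-square test of a contingency table
#'
#' Pearson chi-square without continuity correction, df = (r-1)(c-1). Used
#' for cohort-description statistics such as the sex-by-group association.
#'
#' @param counts numeric r x c matrix of counts.
#' @return list `statistic`, `df`, `p_value`.
#' @export
contingency_chisq <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort_aidhs("contingency table has a zero marginal", "aidhs_validation_error")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected <= 0)) {
    abort_aidhs("all expected counts must be positive", "aidhs_validation_error")
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Stratified performance breakdown
#'
#' Computes per-stratum detection/lateralization percentages for patients
#' (age group at an 18-year adult cut, sex, MRI status, histology, outcome,
#' scan isotropy - whichever columns are present) plus the multivariable
#' correctness regressions.
#'
#' @param predictions predictions tibble (see [performance()]).
#' @param demographics demographics tibble.
#' @return list `strata` (tibble), `detection_regression`,
#'   `lateralization_regression`.
#' @export
performance_breakdown <- function(predictions, demographics) {
  perf <- performance(predictions, demographics)
  ps <- perf$per_subject
  demo <- demographics[match(ps$subject_id, demographics$subject_id), ]
  pat <- ps$group == "patient_HS" & ps$lateralization %in% c("left", "right")

  fac <- list(age_group = ifelse(demo$age_years >= 18, "adult", "pediatric"),
              sex = demo$sex)
  for (cl in c("mri_negative", "histology", "good_outcome", "isotropic")) {
    if (cl %in% names(demo) && !all(is.na(demo[[cl]]))) fac[[cl]] <- as.character(demo[[cl]])
  }
  strata <- list()
  for (nm in names(fac)) {
    vals <- fac[[nm]][pat]
    for (lv in unique(vals[!is.na(vals)])) {
      sel <- pat & !is.na(fac[[nm]]) & fac[[nm]] == lv
      strata[[paste(nm, lv)]] <- tibble::tibble(
        factor = nm, level = lv, n = sum(sel),
        detection_pct = 100 * mean(ps$detection_correct[sel]),
        lateralization_pct = 100 * mean(ps$lateralization_correct[sel]))
    }
  }
  fac_pat <- as.data.frame(lapply(fac, function(v) v[pat]))
  usable <- vapply(fac_pat, function(f) {
    f <- f[!is.na(f)]
    length(unique(f)) >= 2
  }, logical(1))
  fac_pat <- fac_pat[, usable, drop = FALSE]
  det_reg <- stratified_regression(ps$detection_correct[pat], fac_pat)
  lat_reg <- stratified_regression(ps$lateralization_correct[pat], fac_pat)
  list(strata = dplyr::bind_rows(strata),
       detection_regression = det_reg,
       lateralization_regression = lat_reg)
}
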