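#' Train the full detection/lateralization model on a cohort
#'
#' Runs the whole training pipeline: QC gate, vertex preprocessing to
#' per-hemisphere features, leave-one-site-out fold models (each with its own
#' harmonization and normalization state), plus full-cohort components used
#' for reporting - harmonization model, control asymmetry statistics,
#' normative growth charts and per-feature abnormality thresholds - and the
#' out-of-fold performance summary.
#'
#' @param cohort an [aidhs_cohort()].
#' @param harmonize run the multi-site harmonization step.
#' @param dice_threshold QC exclusion threshold.
#' @param qc_override subject ids retained despite failing QC.
#' @param min_site_n minimum site size for harmonization.
#' @param lambda classifier L2 penalty.
#' @param n_sd,fwhm_mm,trim_frac preprocessing parameters.
#' @return object of class `aidhs_model`.
#' @export
aidhs_train <- function(cohort, harmonize = TRUE, dice_threshold = 0.7,
                        qc_override = character(), min_site_n = 20,
                        lambda = 1, n_sd = 5, fwhm_mm = 1.0, trim_frac = 0.01) {
  gate <- qc_filter(cohort, dice_threshold = dice_threshold, override = qc_override)
  cohort <- gate$retained
  demographics <- cohort$demographics
  features <- preprocess_cohort(cohort, n_sd = n_sd, fwhm_mm = fwhm_mm,
                                trim_frac = trim_frac)

  loso <- loso_cv(features, demographics, harmonize = harmonize,
                  min_site_n = min_site_n, lambda = lambda)

  # full-cohort state for reports (bilateral patients may contribute here -
  # they are only barred from classifier training)
  if (harmonize) {
    cm <- fit_combat(features, demographics, min_site_n = min_site_n)
    combat_full <- cm$model
    harm_full <- cm$harmonized
  } else {
    combat_full <- NULL
    harm_full <- skip_combat(features)
  }
  asym_full <- compute_asymmetry(harm_full)
  control_stats <- fit_control_stats(asym_full, demographics)
  norm_full <- normalize_asymmetry(asym_full, control_stats)
  normative <- fit_normative(harm_full, demographics)
  thresholds <- fit_abnormality_thresholds(norm_full, demographics)
  perf <- performance(loso$predictions, demographics)

  structure(list(
    folds = loso$folds,
    loso_predictions = loso$predictions,
    performance = perf$overall,
    combat = combat_full,
    control_stats = control_stats,
    normative = normative,
    thresholds = thresholds,
    qc_excluded = gate$excluded,
    settings = list(harmonize = harmonize, dice_threshold = dice_threshold,
                    min_site_n = min_site_n, lambda = lambda, n_sd = n_sd,
                    fwhm_mm = fwhm_mm, trim_frac = trim_frac),
    version = "1"
  ), class = "aidhs_model")
}

#' @export
print.aidhs_model <- function(x, ...) {
  cat(sprintf("<aidhs_model> %d fold models (%s)\n", length(x$folds),
              paste(names(x$folds), collapse = ", ")))
  cat(sprintf("  out-of-fold: detection %.1f%%, lateralization %.1f%%, specificity %.1f%%\n",
              x$performance$detection_pct, x$performance$lateralization_pct,
              x$performance$specificity_pct))
  invisible(x)
}

#' Predict on a cohort with the trained ensemble
#'
#' Preprocesses the cohort and scores every subject with the ensemble of
#' fold models (averaged probabilities). Sites unknown to a fold's
#' harmonization model have their site effects estimated from the new data,
#' which requires at least `min_site_n` subjects per new site.
#'
#' @param model an [aidhs_train()] model.
#' @param cohort an [aidhs_cohort()] to score.
#' @param apply_qc drop subjects failing the QC gate first.
#' @return predictions tibble (`subject_id`, scores, decisions).
#' @export
aidhs_predict <- function(model, cohort, apply_qc = TRUE) {
  if (apply_qc) {
    cohort <- qc_filter(cohort, model$settings$dice_threshold)$retained
  }
  features <- preprocess_cohort(cohort, n_sd = model$settings$n_sd,
                                fwhm_mm = model$settings$fwhm_mm,
                                trim_frac = model$settings$trim_frac)
  ensemble_predict(model$folds, features, cohort$demographics)
}
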