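#' Left-referenced asymmetry indices
#'
#' For each of the five features the asymmetry index is
#' `AI = 2 * (left - right) / (left + right)`: signed, unitless, bounded in
#' (-2, 2) for positive-valued features, zero under perfect symmetry, and
#' antisymmetric under hemisphere exchange. A single left-referenced vector
#' characterizes the subject; the right hippocampus is its negation.
#'
#' @param features harmonized (or raw, for harmonization-free runs) feature
#'   tibble with both hemispheres per subject.
#' @return tibble: `subject_id` plus one asymmetry column per feature.
#' @export
compute_asymmetry <- function(features) {
  wide <- features_to_wide(features)
  out <- tibble::tibble(subject_id = rownames(wide))
  for (f in aidhs_features()) {
    l <- wide[, paste0(f, "_left")]
    r <- wide[, paste0(f, "_right")]
    denom <- l + r
    if (any(denom <= 0)) {
      bad <- rownames(wide)[which(denom <= 0)[1]]
      abort_aidhs(sprintf("non-positive left+right denominator for feature %s (subject %s)",
                          f, bad), "aidhs_validation_error")
    }
    out[[f]] <- 2 * (l - r) / denom
  }
  out
}

#' Reference asymmetry statistics from healthy controls
#'
#' Stores, per feature, the mean and standard deviation of the raw
#' asymmetries across healthy controls only (disease controls are excluded).
#' These statistics define the typical-asymmetry reference against which all
#' subjects are normalized, and are serialized with the trained model so
#' that held-out data never leak into the normalization.
#'
#' @param asymmetry raw asymmetry tibble from [compute_asymmetry()].
#' @param demographics demographics tibble identifying healthy controls.
#' @return object of class `control_stats`: list with named numeric vectors
#'   `mean` and `sd` and the control count `n`.
#' @export
fit_control_stats <- function(asymmetry, demographics) {
  hc <- demographics$subject_id[demographics$group == "healthy_control"]
  rows <- asymmetry[asymmetry$subject_id %in% hc, ]
  if (nrow(rows) < 2) {
    abort_aidhs("at least 2 healthy controls are required", "aidhs_validation_error")
  }
  mu <- vapply(aidhs_features(), function(f) mean(rows[[f]]), numeric(1))
  sdev <- vapply(aidhs_features(), function(f) sd(rows[[f]]), numeric(1))
  if (any(sdev == 0)) {
    abort_aidhs(sprintf("zero asymmetry SD among healthy controls for: %s",
                        paste(aidhs_features()[sdev == 0], collapse = ", ")),
                "aidhs_validation_error")
  }
  structure(list(mean = mu, sd = sdev, n = nrow(rows)), class = "control_stats")
}

#' Normalize asymmetries against the healthy-control reference
#'
#' `z = (AI - mean_controls) / sd_controls` per feature. When the statistics
#' come from the same sample, the healthy controls normalize to mean 0 and
#' SD 1 exactly.
#'
#' @param asymmetry raw asymmetry tibble.
#' @param stats a `control_stats` object from [fit_control_stats()].
#' @return tibble of normalized asymmetries (same shape as the input).
#' @export
normalize_asymmetry <- function(asymmetry, stats) {
  out <- asymmetry
  for (f in aidhs_features()) {
    out[[f]] <- (asymmetry[[f]] - stats$mean[[f]]) / stats$sd[[f]]
  }
  out
}
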