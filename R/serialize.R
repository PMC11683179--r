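# Versioned JSON serialization of trained models. Matrices are stored with
# explicit dimnames; the normative component is stored as its mean curve
# sampled on a fine age grid plus the residual SD, which is all that centile
# and percentile evaluation require.

mat_to_list <- function(m) {
  list(rows = rownames(m), cols = colnames(m),
       x = lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ])))
}

mat_from_list <- function(l) {
  m <- do.call(rbind, lapply(l$x, as.numeric))
  rownames(m) <- unlist(l$rows)
  colnames(m) <- unlist(l$cols)
  m
}

combat_to_list <- function(model) {
  if (is.null(model)) return(NULL)
  list(features = model$features, sites = model$sites,
       n_per_site = model$n_per_site, cov_cols = model$cov_cols,
       beta_cov = mat_to_list(model$beta_cov),
       grand_mean = model$grand_mean,
       var_pooled = as.numeric(model$var_pooled),
       gamma_star = mat_to_list(model$gamma_star),
       delta_star = mat_to_list(model$delta_star),
       min_site_n = model$min_site_n, version = model$version)
}

combat_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  structure(list(
    features = unlist(x$features), sites = unlist(x$sites),
    n_per_site = as.integer(unlist(x$n_per_site)),
    cov_cols = unlist(x$cov_cols),
    beta_cov = mat_from_list(x$beta_cov),
    grand_mean = as.numeric(unlist(x$grand_mean)),
    var_pooled = setNames(as.numeric(unlist(x$var_pooled)), unlist(x$features)),
    gamma_star = mat_from_list(x$gamma_star),
    delta_star = mat_from_list(x$delta_star),
    min_site_n = x$min_site_n, version = x$version
  ), class = "combat_model")
}

control_stats_to_list <- function(cs) {
  if (is.null(cs)) return(NULL)
  list(mean = as.list(cs$mean), sd = as.list(cs$sd), n = cs$n)
}

control_stats_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  structure(list(mean = unlist(x$mean), sd = unlist(x$sd), n = x$n),
            class = "control_stats")
}

fold_to_list <- function(fold) {
  list(classifier = list(coef = mat_to_list(fold$classifier$coef),
                         features = fold$classifier$features,
                         lambda = fold$classifier$lambda,
                         converged = fold$classifier$converged,
                         n = fold$classifier$n),
       combat = combat_to_list(fold$combat),
       control_stats = control_stats_to_list(fold$control_stats),
       train_sites = fold$train_sites, test_site = fold$test_site,
       harmonize = fold$harmonize, feature_set = fold$feature_set,
       input = fold$input, new_sites = fold$new_sites)
}

fold_from_list <- function(x) {
  clf <- structure(list(coef = mat_from_list(x$classifier$coef),
                        features = unlist(x$classifier$features),
                        lambda = x$classifier$lambda,
                        converged = x$classifier$converged,
                        n = x$classifier$n, classes = aidhs_classes()),
                   class = "aidhs_multinom")
  structure(list(classifier = clf, combat = combat_from_list(x$combat),
                 control_stats = control_stats_from_list(x$control_stats),
                 train_sites = unlist(x$train_sites), test_site = x$test_site,
                 harmonize = x$harmonize, feature_set = unlist(x$feature_set),
                 input = x$input, new_sites = x$new_sites),
            class = "aidhs_fold")
}

#' Save / load a trained model bundle as versioned JSON
#'
#' The bundle stores every fold model (classifier coefficients plus its
#' harmonization and control-statistics state), the full-cohort
#' harmonization model, control statistics, normative charts (grid-sampled)
#' and abnormality thresholds. A reloaded model predicts and reports
#' identically to the in-memory one (normative means are interpolated from
#' the stored grid).
#'
#' @param model an [aidhs_train()] model.
#' @param path JSON file path.
#' @return `aidhs_save_model()`: `path`, invisibly. `aidhs_load_model()`: an
#'   `aidhs_model`.
#' @export
aidhs_save_model <- function(model, path) {
  payload <- list(
    format = "aidhs_model", version = model$version,
    folds = lapply(model$folds, fold_to_list),
    combat = combat_to_list(model$combat),
    control_stats = control_stats_to_list(model$control_stats),
    normative = normative_to_list(model$normative),
    thresholds = model$thresholds,
    settings = model$settings
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}

#' @rdname aidhs_save_model
#' @export
aidhs_load_model <- function(path) {
  x <- jsonlite::read_json(path)
  if (!identical(x$format, "aidhs_model")) {
    abort_aidhs("not an aidhs model file", "aidhs_format_error")
  }
  thr <- dplyr::bind_rows(lapply(x$thresholds, function(r) {
    tibble::tibble(feature = r$feature, side = r$side,
                   threshold = r$threshold %||% NA_real_,
                   slope = r$slope %||% NA_real_, flagged = isTRUE(r$flagged))
  }))
  structure(list(
    folds = lapply(x$folds, fold_from_list),
    loso_predictions = NULL, performance = NULL,
    combat = combat_from_list(x$combat),
    control_stats = control_stats_from_list(x$control_stats),
    normative = normative_from_list(x$normative),
    thresholds = thr,
    qc_excluded = NULL,
    settings = lapply(x$settings, function(v) v),
    version = x$version
  ), class = "aidhs_model")
}
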