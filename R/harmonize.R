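# Multi-site harmonization: parametric empirical-Bayes location/scale batch
# adjustment (Johnson et al. 2007), fitted so the stored model can later be
# applied to new data - including, when explicitly requested, to sites not
# seen at training time (their location/scale is then estimated from the new
# data under the stored standardization model and shrunk with the same
# priors). Biological covariates (age, sex, disease status) are preserved.

combat_design <- function(demographics) {
  sex_m <- as.numeric(demographics$sex == "M")
  grp_pat <- as.numeric(demographics$group == "patient_HS")
  grp_dis <- as.numeric(demographics$group == "disease_control")
  cbind(age = demographics$age_years, sexM = sex_m,
        patient_HS = grp_pat, disease_control = grp_dis)
}

# feature table (2 rows per subject) -> subjects x 10 matrix,
# columns <feature>_<hemi>
features_to_wide <- function(features) {
  w <- tidyr::pivot_wider(
    features[, c("subject_id", "hemisphere", aidhs_features())],
    names_from = "hemisphere",
    values_from = dplyr::all_of(aidhs_features()),
    names_glue = "{.value}_{hemisphere}"
  )
  cols <- as.vector(outer(aidhs_features(), c("left", "right"), paste, sep = "_"))
  m <- as.matrix(w[, cols])
  rownames(m) <- w$subject_id
  m
}

wide_to_features <- function(mat, stage) {
  long <- tibble::tibble(
    subject_id = rep(rownames(mat), times = 2),
    hemisphere = rep(c("left", "right"), each = nrow(mat))
  )
  for (f in aidhs_features()) {
    long[[f]] <- unname(c(mat[, paste0(f, "_left")], mat[, paste0(f, "_right")]))
  }
  long$stage <- stage
  dplyr::arrange(long, .data$subject_id,
                 match(.data$hemisphere, c("left", "right")))
}

# Iterative moment-matched posterior solution for one batch's EB estimates.
combat_eb_batch <- function(s_batch, conv = 1e-4, max_iter = 500) {
  n <- nrow(s_batch)
  g_hat <- colMeans(s_batch)
  d_hat <- apply(s_batch, 2, var)
  g_bar <- mean(g_hat)
  t2 <- var(g_hat)
  m <- mean(d_hat)
  s2 <- var(d_hat)
  a_prior <- (2 * s2 + m^2) / s2
  b_prior <- (m * s2 + m^3) / s2
  g_old <- g_hat
  d_old <- d_hat
  for (it in seq_len(max_iter)) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- colSums((s_batch - matrix(g_new, n, ncol(s_batch), byrow = TRUE))^2)
    d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / abs(g_old), abs(d_new - d_old) / d_old)
    g_old <- g_new
    d_old <- d_new
    if (change < conv) break
  }
  list(gamma_star = g_new, delta_star = d_new,
       gamma_hat = g_hat, delta_hat = d_hat,
       priors = c(gamma_bar = g_bar, tau2 = t2, a = a_prior, b = b_prior))
}

#' Fit the harmonization model
#'
#' Harmonizes the 10 per-hemisphere feature columns (5 features x 2
#' hemispheres, preserving within-subject pairing) across sites while
#' protecting age, sex and disease-status covariate effects. Site locations
#' and scales receive parametric empirical-Bayes shrinkage (normal prior on
#' locations, inverse-gamma on scales).
#'
#' @param features feature tibble from [preprocess_cohort()] (stage `"raw"`).
#' @param demographics demographics tibble covering every subject in
#'   `features`.
#' @param min_site_n minimum subjects per site (harmonization needs a stable
#'   per-scanner estimate; default 20).
#' @return list with `model` (class `combat_model`) and `harmonized`
#'   (feature tibble, stage `"harmonized"`).
#' @export
fit_combat <- function(features, demographics, min_site_n = 20) {
  Y <- features_to_wide(features)
  demo <- demographics[match(rownames(Y), demographics$subject_id), ]
  sites <- as.character(demo$site_id)
  site_levels <- sort(unique(sites))
  if (length(site_levels) < 2) {
    abort_aidhs(paste0("harmonization requires at least 2 sites; with a ",
                       "single site run the pipeline with harmonize = FALSE"),
                "aidhs_parameter_error")
  }
  n_per_site <- table(factor(sites, levels = site_levels))
  too_small <- names(n_per_site)[n_per_site < min_site_n]
  if (length(too_small) > 0) {
    abort_aidhs(sprintf("site(s) below the minimum of %d subjects: %s",
                        min_site_n, paste(too_small, collapse = ", ")),
                "aidhs_parameter_error")
  }
  zero_var <- colnames(Y)[apply(Y, 2, var) == 0]
  if (length(zero_var) > 0) {
    abort_aidhs(sprintf("zero-variance feature column(s): %s",
                        paste(zero_var, collapse = ", ")),
                "aidhs_validation_error")
  }

  Z <- combat_design(demo)
  # constant covariate columns (e.g. a disease-status dummy in an all-control
  # cohort) carry no information and would make the design singular
  cov_cols <- colnames(Z)[apply(Z, 2, var) > 0]
  Z <- Z[, cov_cols, drop = FALSE]
  batch <- model.matrix(~ 0 + factor(sites, levels = site_levels))
  colnames(batch) <- site_levels
  X <- cbind(batch, Z)
  n <- nrow(Y)
  B_hat <- solve(crossprod(X), crossprod(X, Y))
  site_idx <- seq_along(site_levels)
  grand_mean <- as.numeric(n_per_site / n) %*% B_hat[site_idx, , drop = FALSE]
  beta_cov <- B_hat[-site_idx, , drop = FALSE]
  resid <- Y - X %*% B_hat
  var_pooled <- colSums(resid^2) / n

  stand_mean <- matrix(grand_mean, n, ncol(Y), byrow = TRUE) + Z %*% beta_cov
  s_data <- (Y - stand_mean) / matrix(sqrt(var_pooled), n, ncol(Y), byrow = TRUE)

  eb <- lapply(site_levels, function(si) combat_eb_batch(s_data[sites == si, , drop = FALSE]))
  names(eb) <- site_levels
  gamma_star <- do.call(rbind, lapply(eb, `[[`, "gamma_star"))
  delta_star <- do.call(rbind, lapply(eb, `[[`, "delta_star"))
  rownames(gamma_star) <- rownames(delta_star) <- site_levels

  adj <- s_data
  for (si in site_levels) {
    sel <- sites == si
    adj[sel, ] <- sweep(sweep(s_data[sel, , drop = FALSE], 2,
                              gamma_star[si, ], "-"),
                        2, sqrt(delta_star[si, ]), "/")
  }
  harmonized <- adj * matrix(sqrt(var_pooled), n, ncol(Y), byrow = TRUE) + stand_mean

  model <- structure(
    list(features = colnames(Y), sites = site_levels,
         n_per_site = as.integer(n_per_site),
         beta_cov = beta_cov, cov_cols = cov_cols,
         grand_mean = as.numeric(grand_mean),
         var_pooled = var_pooled,
         gamma_star = gamma_star, delta_star = delta_star,
         min_site_n = min_site_n, version = "1"),
    class = "combat_model"
  )
  list(model = model, harmonized = wide_to_features(harmonized, "harmonized"))
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("<combat_model> %d sites (%s), %d feature columns\n",
              length(x$sites), paste(x$sites, collapse = ", "),
              length(x$features)))
  invisible(x)
}

combat_standardize <- function(model, Y, Z) {
  stand_mean <- matrix(model$grand_mean, nrow(Y), ncol(Y), byrow = TRUE) +
    Z %*% model$beta_cov
  sd_mat <- matrix(sqrt(model$var_pooled), nrow(Y), ncol(Y), byrow = TRUE)
  list(s = (Y - stand_mean) / sd_mat, stand_mean = stand_mean, sd_mat = sd_mat)
}

#' Apply a fitted harmonization model to (new) data
#'
#' Deterministic transform using stored parameters. Rows from sites the
#' model was trained on use the stored site effects; rows from unseen sites
#' are handled per `new_sites`: `"error"` (default), `"estimate"` (estimate
#' that site's location/scale from its own rows under the stored
#' standardization model, with the same empirical-Bayes shrinkage - this is
#' how held-out sites are harmonized during cross-validation and requires
#' `min_site_n` rows), or `"passthrough"` (no adjustment, with a warning).
#'
#' @param model a `combat_model` from [fit_combat()].
#' @param features raw feature tibble for the rows to transform.
#' @param demographics matching demographics tibble.
#' @param new_sites unseen-site policy, see above.
#' @return harmonized feature tibble (stage `"harmonized"`).
#' @export
apply_combat <- function(model, features, demographics,
                         new_sites = c("error", "estimate", "passthrough")) {
  new_sites <- match.arg(new_sites)
  Y <- features_to_wide(features)
  zero_var <- colnames(Y)[nrow(Y) > 1 & apply(Y, 2, var) == 0]
  if (length(zero_var) > 0) {
    abort_aidhs(sprintf("zero-variance feature column(s): %s",
                        paste(zero_var, collapse = ", ")),
                "aidhs_validation_error")
  }
  demo <- demographics[match(rownames(Y), demographics$subject_id), ]
  sites <- as.character(demo$site_id)
  unseen <- setdiff(unique(sites), model$sites)
  if (length(unseen) > 0 && new_sites == "error") {
    abort_aidhs(sprintf(
      "site(s) not in the harmonization model: %s (use new_sites = 'estimate' or 'passthrough')",
      paste(unseen, collapse = ", ")), "aidhs_parameter_error")
  }
  Z <- combat_design(demo)[, model$cov_cols %||% colnames(combat_design(demo)),
                           drop = FALSE]
  st <- combat_standardize(model, Y, Z)
  out <- Y
  for (si in unique(sites)) {
    sel <- sites == si
    s_site <- st$s[sel, , drop = FALSE]
    if (si %in% model$sites) {
      g <- model$gamma_star[si, ]
      d <- model$delta_star[si, ]
    } else if (new_sites == "estimate") {
      if (sum(sel) < model$min_site_n) {
        abort_aidhs(sprintf(
          "unseen site %s has %d rows; at least %d are required to estimate site effects",
          si, sum(sel), model$min_site_n), "aidhs_parameter_error")
      }
      eb <- combat_eb_batch(s_site)
      g <- eb$gamma_star
      d <- eb$delta_star
    } else {
      warning(sprintf("site %s unknown to the harmonization model; passing through unadjusted",
                      si), call. = FALSE)
      next
    }
    adj <- sweep(sweep(s_site, 2, g, "-"), 2, sqrt(d), "/")
    out[sel, ] <- adj * st$sd_mat[sel, , drop = FALSE] + st$stand_mean[sel, , drop = FALSE]
  }
  wide_to_features(out, "harmonized")
}

#' Identity (no-op) harmonization
#'
#' Single-site cohorts, or runs where harmonization is deliberately skipped,
#' use this stage transition: values are unchanged, only the stage label
#' advances so downstream steps see a consistent contract.
#'
#' @param features raw feature tibble.
#' @return the same tibble with `stage = "harmonized"`.
#' @export
skip_combat <- function(features) {
  features$stage <- "harmonized"
  features
}
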