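#' Fit normative growth charts
#'
#' For each feature and sex, fits a penalized cubic-spline smooth of the
#' feature against age (`mgcv::gam`, basis dimension 5, REML smoothing
#' selection) on healthy controls, with both hemispheres of each control
#' entering as observations. Centiles follow a Gaussian location model: a
#' smooth age-dependent mean plus a constant residual SD per feature x sex.
#'
#' @param features harmonized feature tibble (healthy controls are selected
#'   via `demographics`).
#' @param demographics demographics tibble.
#' @param k spline basis dimension for age.
#' @param min_controls below this number of healthy controls a warning is
#'   emitted (charts become unstable).
#' @return object of class `normative_model`.
#' @export
fit_normative <- function(features, demographics, k = 5, min_controls = 30) {
  hc <- demographics[demographics$group == "healthy_control", ]
  if (nrow(hc) < min_controls) {
    warning(sprintf("only %d healthy controls; normative charts may be unstable",
                    nrow(hc)), call. = FALSE)
  }
  rows <- dplyr::inner_join(features, hc[, c("subject_id", "age_years", "sex")],
                            by = "subject_id")
  fits <- list()
  for (f in aidhs_features()) {
    for (sx in c("M", "F")) {
      d <- rows[rows$sex == sx, ]
      if (nrow(d) < 10) {
        abort_aidhs(sprintf("sex stratum %s has %d observations; at least 10 required",
                            sx, nrow(d)), "aidhs_validation_error")
      }
      dat <- data.frame(y = d[[f]], age = d$age_years)
      fit <- mgcv::gam(y ~ s(age, bs = "cr", k = k), data = dat, method = "REML")
      fits[[paste(f, sx, sep = ".")]] <- list(
        fit = fit,
        sigma = sqrt(fit$sig2),
        n = nrow(dat),
        age_range = range(dat$age)
      )
    }
  }
  structure(list(fits = fits, k = k, n_controls = nrow(hc),
                 features = aidhs_features(), version = "1"),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model> %d feature x sex growth charts from %d healthy controls\n",
              length(x$fits), x$n_controls))
  invisible(x)
}

normative_component <- function(model, feature, sex) {
  comp <- model$fits[[paste(feature, sex, sep = ".")]]
  if (is.null(comp)) {
    abort_aidhs(sprintf("no normative chart for feature %s, sex %s", feature, sex),
                "aidhs_parameter_error")
  }
  comp
}

normative_mean <- function(model, feature, sex, ages) {
  comp <- normative_component(model, feature, sex)
  if (!is.null(comp$fit)) {
    as.numeric(predict(comp$fit, newdata = data.frame(age = ages)))
  } else {
    # deserialized model: interpolate the stored mean curve, with flat
    # (constant) extension outside the stored support
    approx(comp$grid_age, comp$grid_mu, xout = ages, rule = 2)$y
  }
}

#' Evaluate a centile curve
#'
#' `curve(age) = mu(age, sex) + z_p * sigma`, with `z_p` the standard normal
#' quantile of the requested percentile. Ages outside the fitting support
#' are flagged via the `extrapolated` column.
#'
#' @param model a [fit_normative()] model.
#' @param feature,sex chart selector.
#' @param percentile percentile in (0, 100).
#' @param ages numeric vector of ages (years).
#' @return tibble `age`, `value`, `extrapolated`.
#' @export
centile_curve <- function(model, feature, sex, percentile, ages) {
  if (percentile <= 0 || percentile >= 100) {
    abort_aidhs("percentile must be strictly inside (0, 100)", "aidhs_parameter_error")
  }
  comp <- normative_component(model, feature, sex)
  mu <- normative_mean(model, feature, sex, ages)
  extrapolated <- ages < comp$age_range[1] | ages > comp$age_range[2]
  if (any(extrapolated)) {
    warning(sprintf("%d age(s) outside the normative support [%.1f, %.1f]",
                    sum(extrapolated), comp$age_range[1], comp$age_range[2]),
            call. = FALSE)
  }
  tibble::tibble(age = ages,
                 value = mu + qnorm(percentile / 100) * comp$sigma,
                 extrapolated = extrapolated)
}

#' Percentile score of an observed value
#'
#' `100 * Phi((value - mu(age, sex)) / sigma)`, clipped to (0.1, 99.9) for
#' display so a report never prints a categorical 0 or 100.
#'
#' @inheritParams centile_curve
#' @param value observed feature value(s).
#' @param age age(s) in years, recycled against `value`.
#' @return numeric percentile score(s) in (0.1, 99.9).
#' @export
percentile_score <- function(model, feature, value, age, sex) {
  comp <- normative_component(model, feature, sex)
  mu <- normative_mean(model, feature, sex, age)
  p <- 100 * pnorm((value - mu) / comp$sigma)
  pmin(pmax(p, 0.1), 99.9)
}

#' Age, sex and hemisphere effects on harmonized features
#'
#' One ordinary least-squares model per feature on healthy controls (both
#' hemispheres as observations): `value ~ hemisphere + sex + age`. Reference
#' levels: left hemisphere, female.
#'
#' @param features harmonized feature tibble.
#' @param demographics demographics tibble.
#' @return tibble `feature`, `term`, `estimate`, `std_error`, `p_value`.
#' @export
covariate_regression <- function(features, demographics) {
  hc <- demographics[demographics$group == "healthy_control", ]
  rows <- dplyr::inner_join(features, hc[, c("subject_id", "age_years", "sex")],
                            by = "subject_id")
  out <- list()
  for (f in aidhs_features()) {
    dat <- data.frame(
      y = rows[[f]],
      hemisphere = factor(rows$hemisphere, levels = c("left", "right")),
      sex = factor(rows$sex, levels = c("F", "M")),
      age = rows$age_years
    )
    fit <- lm(y ~ hemisphere + sex + age, data = dat)
    if (fit$rank < 4) {
      abort_aidhs(sprintf("rank-deficient design for feature %s", f),
                  "aidhs_validation_error")
    }
    sm <- summary(fit)$coefficients
    terms <- rownames(sm)[-1]
    out[[f]] <- tibble::tibble(
      feature = f, term = terms,
      estimate = sm[-1, "Estimate"],
      std_error = sm[-1, "Std. Error"],
      p_value = sm[-1, "Pr(>|t|)"]
    )
  }
  dplyr::bind_rows(out)
}

# Serializable form: sample the mean curve on a fine age grid.
normative_to_list <- function(model, grid_n = 200) {
  comps <- lapply(names(model$fits), function(nm) {
    comp <- model$fits[[nm]]
    ages <- seq(comp$age_range[1], comp$age_range[2], length.out = grid_n)
    mu <- if (!is.null(comp$fit)) {
      as.numeric(predict(comp$fit, newdata = data.frame(age = ages)))
    } else {
      approx(comp$grid_age, comp$grid_mu, xout = ages, rule = 2)$y
    }
    list(grid_age = ages, grid_mu = mu, sigma = comp$sigma, n = comp$n,
         age_range = comp$age_range)
  })
  names(comps) <- names(model$fits)
  list(fits = comps, k = model$k, n_controls = model$n_controls,
       features = model$features, version = model$version)
}

normative_from_list <- function(x) {
  fits <- lapply(x$fits, function(comp) {
    list(fit = NULL,
         grid_age = as.numeric(comp$grid_age),
         grid_mu = as.numeric(comp$grid_mu),
         sigma = as.numeric(comp$sigma), n = as.integer(comp$n),
         age_range = as.numeric(comp$age_range))
  })
  structure(list(fits = fits, k = x$k, n_controls = x$n_controls,
                 features = unlist(x$features), version = x$version),
            class = "normative_model")
}
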