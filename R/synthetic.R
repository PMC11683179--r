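# Seeded synthetic cohorts emulating hippocampal segmentation-tool outputs:
# demographics, per-vertex surface metrics, volumes and Dice QC scores, with
# age/sex trajectories, hemispheric offsets, site batch effects and
# ipsilateral HS effects in the directions seen in sclerotic hippocampi
# (volume, thickness, gyrification reduced; mean and intrinsic curvature
# increased).

#' Default per-feature generative parameters
#'
#' Age trajectories use a monotone saturating form
#' `mu(age) = base + range * (1 - exp(-age / tau))`, mimicking the childhood
#' rise and adult plateau of hippocampal morphometry. Magnitudes are set to
#' plausible adult scales (volume ~3000 mm^3, thickness ~1.6 mm,
#' gyrification ~3, small positive curvatures); sex and hemisphere offsets
#' are placed on the features that show them in healthy cohorts (volume,
#' thickness, mean curvature differ by sex; gyrification and intrinsic
#' curvature differ by hemisphere).
#'
#' @return tibble of per-feature generative parameters.
#' @export
sim_feature_params <- function() {
  tibble::tibble(
    feature = aidhs_features(),
    base = c(2200, 1.30, 2.60, 0.150, 0.0240),
    range = c(1000, 0.40, 0.50, 0.020, 0.0050),
    tau = c(8, 10, 8, 15, 15),
    sex_offset_m = c(150, 0.03, 0, 0.005, 0),      # male minus female
    hemi_offset = c(0, 0, 0.05, 0, 0.001),          # left minus right
    subject_sd = c(200, 0.08, 0.15, 0.012, 0.0020), # shared across hemispheres
    hemi_sd = c(60, 0.03, 0.05, 0.004, 0.0007),     # independent per hemisphere
    vertex_sd = c(0, 0.15, 0.30, 0.030, 0.0060)     # spatial noise (volume has no vertices)
  )
}

#' Simulation configuration
#'
#' Defaults define the reference study conditions: 4 sites, each contributing
#' 50 left-HS patients, 50 right-HS patients, 50 healthy and 50 disease
#' controls; additive site shifts of 0/+5/-4/+2% of each feature's adult
#' scale with multiplicative site scales 1/1.08/0.95/1.02; ages uniform on
#' 4-60 years. The ipsilateral HS multipliers are calibrated so that the
#' fraction of patients breaching the healthy 5th/95th centile per feature
#' matches the prevalences reported in surgical HS cohorts (about 90% for
#' volume, 63% thickness, 88% gyrification, 67% mean and 70% intrinsic
#' curvature).
#'
#' @param n_left_hs,n_right_hs,n_healthy,n_disease subjects per group per site.
#' @param n_bilateral bilateral HS patients per site (held out from
#'   training; default 0).
#' @param sites site ids.
#' @param site_shift_frac per-site additive shift, as a fraction of each
#'   feature's adult scale (`base + range`).
#' @param site_scale per-site multiplicative scale.
#' @param age_range uniform age sampling range (years).
#' @param female_prob probability of sex `F`.
#' @param hs_effects named ipsilateral multipliers per feature.
#' @param effect_scale exponent on the multipliers: 1 = configured effects,
#'   0 = null cohort (all multipliers 1).
#' @param feature_params per-feature generative parameters
#'   ([sim_feature_params()]).
#' @param outlier_rate per-vertex probability of an injected outlier spike.
#' @param qc_fail_rate probability of an injected segmentation failure
#'   (Dice drawn below 0.7).
#' @param grid_n_ap,grid_n_pd,spacing_mm surface grid ([make_surface()]).
#' @param seed mandatory RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_left_hs = 50, n_right_hs = 50, n_healthy = 50,
                       n_disease = 50, n_bilateral = 0,
                       sites = paste0("site", 1:4),
                       site_shift_frac = c(0, 0.05, -0.04, 0.02),
                       site_scale = c(1, 1.08, 0.95, 1.02),
                       age_range = c(4, 60), female_prob = 0.55,
                       hs_effects = c(volume = 0.82, thickness = 0.90,
                                      gyrification = 0.86, curv_mean = 1.16,
                                      curv_intrinsic = 1.17),
                       effect_scale = 1,
                       feature_params = sim_feature_params(),
                       outlier_rate = 0.001, qc_fail_rate = 0.02,
                       grid_n_ap = 24, grid_n_pd = 12, spacing_mm = 0.5,
                       seed) {
  if (missing(seed)) abort_aidhs("seed is mandatory", "aidhs_parameter_error")
  if (length(site_shift_frac) != length(sites) ||
      length(site_scale) != length(sites)) {
    abort_aidhs("site_shift_frac and site_scale must match the number of sites",
                "aidhs_parameter_error")
  }
  mult <- hs_effects[aidhs_features()]^effect_scale
  if (effect_scale > 0 &&
      (any(mult[c("volume", "thickness", "gyrification")] >= 1) ||
       any(mult[c("curv_mean", "curv_intrinsic")] <= 1))) {
    abort_aidhs(paste0("HS multipliers must reduce volume/thickness/gyrification ",
                       "and increase the curvatures"), "aidhs_parameter_error")
  }
  if (any(feature_params$subject_sd < 0) || any(feature_params$hemi_sd < 0) ||
      any(feature_params$vertex_sd < 0)) {
    abort_aidhs("all SDs must be non-negative", "aidhs_parameter_error")
  }
  structure(list(
    n_left_hs = n_left_hs, n_right_hs = n_right_hs, n_healthy = n_healthy,
    n_disease = n_disease, n_bilateral = n_bilateral, sites = sites,
    site_shift_frac = site_shift_frac, site_scale = site_scale,
    age_range = age_range, female_prob = female_prob,
    hs_multipliers = mult, effect_scale = effect_scale,
    feature_params = feature_params, outlier_rate = outlier_rate,
    qc_fail_rate = qc_fail_rate, grid_n_ap = grid_n_ap,
    grid_n_pd = grid_n_pd, spacing_mm = spacing_mm, seed = seed
  ), class = "sim_config")
}

sim_trajectory <- function(par, age) {
  par$base + par$range * (1 - exp(-age / par$tau))
}

#' Simulate a synthetic cohort
#'
#' Per subject, hemisphere and feature the hemispheric scalar is
#' `trajectory(age) + sex offset + signed hemisphere offset + site shift +
#' subject random effect + hemisphere noise`, multiplied by the site scale;
#' ipsilateral features of HS subjects are additionally multiplied by the
#' configured effect multipliers (both hemispheres for bilateral patients).
#' Vertex metric fields are the hemispheric scalar plus a fixed
#' anterior-posterior pattern, spatially smoothed vertex noise and sparse
#' injected outlier spikes; volumes carry no vertex component. Dice scores
#' are high-valued with configurable injected failures. The generator is
#' fully deterministic given its seed.
#'
#' @param config a [sim_config()].
#' @return an [aidhs_cohort()] (truth lives in the demographics `group` /
#'   `lateralization` columns).
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  surface <- make_surface(config$grid_n_ap, config$grid_n_pd, config$spacing_mm)
  nv <- n_vertices(surface)
  fp <- config$feature_params
  feature_scale <- fp$base + fp$range

  # uniform 1-ring averaging operator for spatial noise smoothness
  adj <- surface_adjacency(surface) + Matrix::Diagonal(nv)
  Wu <- Matrix::Diagonal(x = 1 / Matrix::rowSums(adj)) %*% adj
  ap_pattern <- sin(2 * pi * surface$ap_coord)

  groups <- c(rep("left_hs", config$n_left_hs), rep("right_hs", config$n_right_hs),
              rep("bilateral", config$n_bilateral),
              rep("healthy", config$n_healthy), rep("disease", config$n_disease))

  demo_rows <- list()
  metrics <- list()
  vol_rows <- list()
  qc_rows <- list()

  for (si in seq_along(config$sites)) {
    site <- config$sites[si]
    shift <- config$site_shift_frac[si] * feature_scale
    scale <- config$site_scale[si]
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      sid <- sprintf("%s_s%03d", site, gi)
      age <- runif(1, config$age_range[1], config$age_range[2])
      sex <- if (runif(1) < config$female_prob) "F" else "M"
      group <- switch(g, left_hs = , right_hs = , bilateral = "patient_HS",
                      healthy = "healthy_control", disease = "disease_control")
      lat <- switch(g, left_hs = "left", right_hs = "right",
                    bilateral = "bilateral", "none")

      subj_eff <- rnorm(5, 0, fp$subject_sd)
      mats <- list()
      for (h in c("left", "right")) {
        hemi_sign <- if (h == "left") 0.5 else -0.5
        scalar <- sim_trajectory(fp, age) +
          fp$sex_offset_m * (sex == "M") +
          fp$hemi_offset * hemi_sign +
          shift + subj_eff + rnorm(5, 0, fp$hemi_sd)
        ipsi <- (lat == "bilateral") || (lat == h)
        if (ipsi) scalar <- scalar * config$hs_multipliers
        scalar <- scalar * scale
        names(scalar) <- fp$feature
        if (any(scalar[c("volume", "thickness", "gyrification")] <= 0)) {
          abort_aidhs("configuration implies non-positive feature values",
                      "aidhs_validation_error")
        }

        mat <- matrix(NA_real_, nrow = nv, ncol = 4,
                      dimnames = list(NULL, surface_features()))
        for (k in which(fp$feature %in% surface_features())) {
          f <- fp$feature[k]
          vsd <- fp$vertex_sd[k] * scale
          noise <- as.numeric(Wu %*% (Wu %*% rnorm(nv, 0, vsd)))
          field <- scalar[[f]] + 0.5 * vsd * ap_pattern + noise
          n_out <- rbinom(1, nv, config$outlier_rate)
          if (n_out > 0 && vsd > 0) {
            idx <- sample.int(nv, n_out)
            field[idx] <- scalar[[f]] + sample(c(-1, 1), n_out, replace = TRUE) * 8 * vsd
          }
          mat[, f] <- field
        }
        mats[[h]] <- mat
        vol_rows[[paste(sid, h)]] <- tibble::tibble(
          subject_id = sid, hemisphere = h, volume = unname(scalar[["volume"]]))
      }
      metrics[[sid]] <- mats

      fail <- runif(1) < config$qc_fail_rate
      dice <- if (fail) {
        c(runif(1, 0.4, 0.69), rbeta(1, 40, 8))
      } else {
        0.70 + 0.29 * rbeta(2, 8, 4)
      }
      qc_rows[[sid]] <- tibble::tibble(subject_id = sid,
                                       dice_left = dice[1], dice_right = dice[2])

      is_pat <- group == "patient_HS"
      demo_rows[[sid]] <- tibble::tibble(
        subject_id = sid, site_id = site, group = group, lateralization = lat,
        age_years = age, sex = sex,
        mri_negative = if (is_pat) runif(1) < 0.156 else NA,
        histology = if (is_pat) sample(c("HS1", "HS2", "HS3", "nonspecified"),
                                       1, prob = c(0.39, 0.19, 0.05, 0.37)) else NA_character_,
        good_outcome = if (is_pat) runif(1) < 0.72 else NA,
        icv_mm3 = rnorm(1, 1.45e6, 1.2e5),
        scan_field = "3T",
        isotropic = runif(1) < 0.645
      )
    }
  }
  aidhs_cohort(
    demographics = dplyr::bind_rows(demo_rows),
    surface = surface,
    metrics = metrics,
    volumes = dplyr::bind_rows(vol_rows),
    qc = dplyr::bind_rows(qc_rows)
  )
}
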