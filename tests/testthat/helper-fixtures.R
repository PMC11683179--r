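# Shared fixtures, built in code at test time.

# Flat uniform grid with the package's standard topology (vertices coplanar,
# so mesh distances are Euclidean in the plane).
flat_grid_surface <- function(n_ap = 21, n_pd = 21, spacing = 0.5) {
  surf <- make_surface(n_ap, n_pd, spacing)
  i <- rep(seq_len(n_ap), times = n_pd)
  j <- rep(seq_len(n_pd), each = n_ap)
  surf$vertices <- cbind((i - 1) * spacing, (j - 1) * spacing, 0)
  surf
}

# Feature-level synthetic cohort (no vertex data): fast generator for the
# harmonization / classifier / normative layers. Per-hemisphere feature
# values around plausible scales with an optional additive site shift (in
# units of the within-site SD; scalar or per-feature vector of length 5),
# an age slope on volume, and an HS effect applied ipsilaterally.
feature_cohort <- function(n_per_group = 25, sites = c("A", "B"),
                           site_shift = 0, age_slope_volume = 0,
                           hs_multiplier = NULL, seed = 1,
                           hemi_sd_frac = 0.02, subj_sd_frac = 0.06) {
  set.seed(seed)
  base <- c(volume = 3000, thickness = 1.6, gyrification = 3,
            curv_mean = 0.17, curv_intrinsic = 0.028)
  if (is.null(hs_multiplier)) {
    hs_multiplier <- c(volume = 0.82, thickness = 0.90, gyrification = 0.86,
                       curv_mean = 1.16, curv_intrinsic = 1.17)
  }
  groups <- c("left_hs", "right_hs", "healthy", "disease")
  demo_rows <- list(); feat_rows <- list()
  for (s in seq_along(sites)) {
    for (g in groups) {
      for (k in seq_len(n_per_group)) {
        sid <- sprintf("%s_%s_%02d", sites[s], g, k)
        age <- runif(1, 5, 60)
        sex <- sample(c("M", "F"), 1)
        subj <- rnorm(5, 0, subj_sd_frac * base)
        lat <- switch(g, left_hs = "left", right_hs = "right", "none")
        demo_rows[[sid]] <- tibble::tibble(
          subject_id = sid, site_id = sites[s],
          group = switch(g, left_hs = , right_hs = "patient_HS",
                         healthy = "healthy_control", "disease_control"),
          lateralization = lat, age_years = age, sex = sex)
        for (h in c("left", "right")) {
          v <- base + subj + rnorm(5, 0, hemi_sd_frac * base)
          v[["volume"]] <- v[["volume"]] + age_slope_volume * age
          sd_frac <- sqrt(subj_sd_frac^2 + hemi_sd_frac^2)
          if (s > 1) v <- v + rep(site_shift, length.out = 5) * sd_frac * base
          if (lat == h) v <- v * hs_multiplier
          feat_rows[[paste(sid, h)]] <- tibble::tibble(
            subject_id = sid, hemisphere = h, volume = v[["volume"]],
            thickness = v[["thickness"]], gyrification = v[["gyrification"]],
            curv_mean = v[["curv_mean"]], curv_intrinsic = v[["curv_intrinsic"]],
            stage = "raw")
        }
      }
    }
  }
  list(demographics = dplyr::bind_rows(demo_rows),
       features = dplyr::bind_rows(feat_rows))
}

# Small full cohort reused by several files (vertex-level, 4 sites).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_left_hs = 8, n_right_hs = 8, n_healthy = 12,
                        n_disease = 8, grid_n_ap = 12, grid_n_pd = 6,
                        qc_fail_rate = 0, seed = 42)
      cache <<- simulate_cohort(cfg)
    }
    cache
  }
})

small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- aidhs_train(small_cohort(), min_site_n = 10)
    cache
  }
})

expect_tibble_equal <- function(a, b, ...) {
  testthat::expect_equal(as.data.frame(a), as.data.frame(b), ...)
}
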