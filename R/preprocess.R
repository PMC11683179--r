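#' Iterative outlier vertex replacement
#'
#' Vertices falling outside `n_sd` standard deviations of the field's mean
#' are replaced by the mean of their non-outlier 1-ring neighbours; when an
#' outlier has no non-outlier 1-ring neighbour, the nearest non-outlier
#' vertices by breadth-first search are used. Mean and SD are recomputed
#' after each sweep and the loop stops when no vertex is flagged or
#' `max_iter` is reached (with a warning).
#'
#' @param values numeric per-vertex field.
#' @param surface the [hip_surface()] the field lives on.
#' @param n_sd flagging threshold in SD units (> 0).
#' @param max_iter maximum number of sweeps.
#' @return the cleaned per-vertex field.
#' @export
replace_outlier_vertices <- function(values, surface, n_sd = 5, max_iter = 10) {
  if (n_sd <= 0) abort_aidhs("n_sd must be positive", "aidhs_parameter_error")
  if (length(values) != n_vertices(surface)) {
    abort_aidhs("metric length does not match the surface vertex count",
                "aidhs_format_error")
  }
  adj <- surface_adjacency(surface)
  v <- as.numeric(values)
  for (iter in seq_len(max_iter)) {
    m <- mean(v)
    s <- sd(v)
    if (s == 0) return(v)  # constant field: no outliers by definition
    out <- abs(v - m) > n_sd * s
    if (!any(out)) return(v)
    if (all(out)) {
      abort_aidhs("all vertices flagged as outliers; field is degenerate",
                  "aidhs_validation_error")
    }
    ok <- !out
    nb_sum <- as.numeric(adj %*% (v * ok))
    nb_n <- as.numeric(adj %*% ok)
    idx <- which(out)
    for (i in idx) {
      if (nb_n[i] > 0) {
        v[i] <- nb_sum[i] / nb_n[i]
      } else {
        # all 1-ring neighbours are outliers too: expand by BFS until a
        # non-outlier frontier is reached, then average that frontier
        frontier <- i
        seen <- rep(FALSE, length(v))
        seen[i] <- TRUE
        repeat {
          nxt <- which(as.numeric(adj[, frontier, drop = FALSE] %*%
                                    rep(1, length(frontier))) > 0 & !seen)
          if (length(nxt) == 0) break
          hit <- nxt[ok[nxt]]
          if (length(hit) > 0) {
            v[i] <- mean(v[hit])
            break
          }
          seen[nxt] <- TRUE
          frontier <- nxt
        }
      }
    }
  }
  m <- mean(v)
  s <- sd(v)
  if (s > 0 && any(abs(v - m) > n_sd * s)) {
    warning("outlier replacement reached max_iter with vertices still flagged",
            call. = FALSE)
  }
  v
}

#' Geodesic Gaussian smoothing operator
#'
#' Smoothing is iterated 1-ring neighbour-weighted averaging: one sweep
#' applies row-normalized weights `exp(-d^2 / (2 * sigma_step^2))` over mesh
#' edges (self distance 0). The number of sweeps and the per-sweep bandwidth
#' are calibrated so that the composite kernel's second moment matches a
#' Gaussian of the requested FWHM (`sigma = FWHM / 2.3548`) on the mesh; by
#' the central limit theorem the iterated kernel converges to that Gaussian.
#'
#' @param surface a [hip_surface()].
#' @param fwhm_mm requested kernel full-width at half-maximum in mm (>= 0).
#' @return a list with the sparse one-sweep operator `W` (rows sum to 1) and
#'   the sweep count `n_iter`; `NULL` operator when `fwhm_mm = 0` (identity).
#' @export
smooth_operator <- function(surface, fwhm_mm = 1.0) {
  if (fwhm_mm < 0) abort_aidhs("fwhm_mm must be non-negative", "aidhs_parameter_error")
  if (fwhm_mm == 0) {
    return(structure(list(W = NULL, n_iter = 0L, fwhm_mm = 0),
                     class = "aidhs_smoother"))
  }
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  target <- 2 * sigma^2  # radial second moment of a 2-D Gaussian

  D <- surface_edge_lengths(surface)
  n <- nrow(D)
  # second moment of one row-normalized sweep with bandwidth s, averaged
  # over vertices (self weight exp(0) = 1)
  moment1 <- function(s) {
    w <- D
    w@x <- exp(-(D@x^2) / (2 * s^2))
    rs <- Matrix::rowSums(w)
    mean(as.numeric(Matrix::rowSums(w * D^2)) / (1 + rs))
  }
  h <- mean(D@x)
  m1_max <- moment1(1e6 * h)  # uniform-weight limit
  # keep the per-sweep bandwidth near the edge scale (a heavily truncated
  # 1-ring step composes toward a compound-Poisson kernel, not a Gaussian),
  # then fine-solve the bandwidth so the composite second moment is exact
  n_iter <- max(1L, as.integer(ceiling(target / moment1(0.55 * h) - 0.15)))
  while (target / n_iter > 0.999 * m1_max) n_iter <- n_iter + 1L
  f <- function(s) n_iter * moment1(s) - target
  sigma_step <- tryCatch(
    stats::uniroot(f, lower = 1e-4 * h, upper = 1e6 * h, tol = 1e-10)$root,
    error = function(e) {
      abort_aidhs("could not calibrate smoothing kernel on this mesh",
                  "aidhs_parameter_error")
    }
  )
  W <- D
  W@x <- exp(-(D@x^2) / (2 * sigma_step^2))
  W <- W + Matrix::Diagonal(n)
  W <- Matrix::Diagonal(x = 1 / Matrix::rowSums(W)) %*% W
  structure(list(W = W, n_iter = n_iter, fwhm_mm = fwhm_mm,
                 sigma_step = sigma_step),
            class = "aidhs_smoother")
}

apply_smoother <- function(smoother, values) {
  if (smoother$n_iter == 0L) return(as.numeric(values))
  v <- values
  for (k in seq_len(smoother$n_iter)) v <- smoother$W %*% v
  as.numeric(v)
}

#' Smooth a per-vertex metric
#'
#' @inheritParams replace_outlier_vertices
#' @param fwhm_mm Gaussian kernel FWHM in mm; `0` is the identity.
#' @param smoother optional precomputed [smooth_operator()] (reused across
#'   subjects for speed).
#' @return smoothed per-vertex field.
#' @export
smooth_metric <- function(values, surface, fwhm_mm = 1.0, smoother = NULL) {
  if (length(values) != n_vertices(surface)) {
    abort_aidhs("metric length does not match the surface vertex count",
                "aidhs_format_error")
  }
  if (is.null(smoother)) smoother <- smooth_operator(surface, fwhm_mm)
  apply_smoother(smoother, values)
}

#' Anterior-posterior trimmed mean
#'
#' Averages a per-vertex field over vertices whose anterior-posterior
#' coordinate lies within the central `[trim_frac, 1 - trim_frac]` quantile
#' band, excluding the highly variable extremes of the hippocampal head and
#' tail. Trimming is by coordinate quantile, so it is mesh-resolution
#' independent.
#'
#' @inheritParams replace_outlier_vertices
#' @param trim_frac fraction trimmed at each extreme (`0 <= trim_frac < 0.5`).
#' @return scalar mean.
#' @export
trimmed_mean <- function(values, surface, trim_frac = 0.01) {
  if (trim_frac < 0 || trim_frac >= 0.5) {
    abort_aidhs("trim_frac must be in [0, 0.5)", "aidhs_parameter_error")
  }
  if (length(values) != n_vertices(surface)) {
    abort_aidhs("metric length does not match the surface vertex count",
                "aidhs_format_error")
  }
  ap <- surface$ap_coord
  q <- quantile(ap, c(trim_frac, 1 - trim_frac), names = FALSE)
  keep <- ap >= q[1] & ap <= q[2]
  if (!any(keep)) {
    abort_aidhs("trimming removed every vertex", "aidhs_validation_error")
  }
  mean(values[keep])
}

#' Aggregate one subject's vertex metrics to per-hemisphere features
#'
#' Applies the fixed preprocessing order - outlier replacement, smoothing,
#' anterior-posterior trimmed mean - to each surface feature of each
#' hemisphere, and passes volumes through untouched.
#'
#' @param metrics list with `left` and `right` vertex-by-feature matrices.
#' @param volumes named numeric, `c(left = ..., right = ...)` in mm^3.
#' @param surface the shared [hip_surface()].
#' @param n_sd,fwhm_mm,trim_frac preprocessing parameters.
#' @param smoother optional precomputed [smooth_operator()].
#' @param subject_id id used in the output rows.
#' @return tibble with one row per hemisphere: `subject_id`, `hemisphere`,
#'   the five features, `stage = "raw"`.
#' @export
aggregate_subject <- function(metrics, volumes, surface, subject_id = "subject",
                              n_sd = 5, fwhm_mm = 1.0, trim_frac = 0.01,
                              smoother = NULL) {
  if (!all(c("left", "right") %in% names(metrics))) {
    abort_aidhs("both hemispheres required", "aidhs_validation_error")
  }
  if (!all(c("left", "right") %in% names(volumes))) {
    abort_aidhs("volumes required for both hemispheres", "aidhs_validation_error")
  }
  if (is.null(smoother)) smoother <- smooth_operator(surface, fwhm_mm)
  rows <- lapply(c("left", "right"), function(h) {
    mat <- metrics[[h]]
    vals <- vapply(surface_features(), function(f) {
      v <- replace_outlier_vertices(mat[, f], surface, n_sd = n_sd)
      v <- apply_smoother(smoother, v)
      trimmed_mean(v, surface, trim_frac = trim_frac)
    }, numeric(1))
    tibble::tibble(subject_id = subject_id, hemisphere = h,
                   volume = unname(volumes[[h]]),
                   thickness = vals[["thickness"]],
                   gyrification = vals[["gyrification"]],
                   curv_mean = vals[["curv_mean"]],
                   curv_intrinsic = vals[["curv_intrinsic"]],
                   stage = "raw")
  })
  dplyr::bind_rows(rows)
}

#' Preprocess a whole cohort to per-hemisphere features
#'
#' @param cohort an [aidhs_cohort()].
#' @inheritParams aggregate_subject
#' @return feature tibble with two rows (hemispheres) per subject.
#' @export
preprocess_cohort <- function(cohort, n_sd = 5, fwhm_mm = 1.0, trim_frac = 0.01) {
  smoother <- smooth_operator(cohort$surface, fwhm_mm)
  vols <- cohort$volumes
  rows <- lapply(cohort$demographics$subject_id, function(sid) {
    v <- vols[vols$subject_id == sid, ]
    aggregate_subject(
      cohort$metrics[[sid]],
      volumes = setNames(v$volume, v$hemisphere),
      surface = cohort$surface, subject_id = sid,
      n_sd = n_sd, fwhm_mm = fwhm_mm, trim_frac = trim_frac,
      smoother = smoother
    )
  })
  dplyr::bind_rows(rows)
}
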