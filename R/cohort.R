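#' Cohort container and demographics schema
#'
#' An `aidhs_cohort` bundles everything the pipeline consumes for one cohort:
#' a demographics table, the shared reference surface, per-subject per-vertex
#' metrics for the four surface features, per-hemisphere volumes, and
#' segmentation QC (Dice) records.
#'
#' Demographics columns (one row per subject, unknowns as `NA` / empty
#' cells): `subject_id`, `site_id`, `group` (one of `patient_HS`,
#' `disease_control`, `healthy_control`), `lateralization` (`left`, `right`,
#' `bilateral` for patients; `none` otherwise), `age_years` (> 3, decimal
#' years), `sex` (`M`/`F`), and optional `mri_negative`, `histology` (`HS1`,
#' `HS2`, `HS3`, `nonspecified`), `good_outcome`, `icv_mm3`, `scan_field`
#' (`1.5T`/`3T`), `isotropic`.
#'
#' @param demographics tibble as described above.
#' @param surface the shared [hip_surface()].
#' @param metrics named list: `metrics[[subject_id]][[hemisphere]]` is an
#'   `n_vertices x 4` matrix with columns `thickness`, `gyrification`,
#'   `curv_mean`, `curv_intrinsic`.
#' @param volumes tibble `subject_id`, `hemisphere`, `volume` (mm^3).
#' @param qc tibble `subject_id`, `dice_left`, `dice_right`.
#' @return an object of class `aidhs_cohort`.
#' @export
aidhs_cohort <- function(demographics, surface, metrics, volumes, qc) {
  cohort <- structure(
    list(demographics = tibble::as_tibble(demographics), surface = surface,
         metrics = metrics, volumes = tibble::as_tibble(volumes),
         qc = tibble::as_tibble(qc)),
    class = "aidhs_cohort"
  )
  validate_cohort(cohort)
  cohort
}

#' @export
print.aidhs_cohort <- function(x, ...) {
  grp <- table(x$demographics$group)
  cat(sprintf("<aidhs_cohort> %d subjects across %d sites (%s); %d-vertex surface\n",
              nrow(x$demographics), length(unique(x$demographics$site_id)),
              paste(names(grp), grp, sep = ": ", collapse = ", "),
              n_vertices(x$surface)))
  invisible(x)
}

required_demographics_cols <- function() {
  c("subject_id", "site_id", "group", "lateralization", "age_years", "sex")
}

validate_demographics <- function(demographics) {
  missing <- setdiff(required_demographics_cols(), names(demographics))
  if (length(missing) > 0) {
    abort_aidhs(
      sprintf("demographics table is missing required column(s): %s",
              paste(missing, collapse = ", ")),
      "aidhs_schema_error"
    )
  }
  if (anyDuplicated(demographics$subject_id)) {
    abort_aidhs("duplicated subject_id in demographics", "aidhs_schema_error")
  }
  bad_group <- setdiff(unique(demographics$group), aidhs_groups())
  if (length(bad_group) > 0) {
    abort_aidhs(sprintf("unknown group value(s): %s",
                        paste(bad_group, collapse = ", ")),
                "aidhs_schema_error")
  }
  if (any(demographics$age_years <= 3)) {
    abort_aidhs("all subjects must be more than 3 years old at scan",
                "aidhs_validation_error")
  }
  if (!all(demographics$sex %in% c("M", "F"))) {
    abort_aidhs("sex must be coded as 'M' or 'F'", "aidhs_schema_error")
  }
  pat <- demographics$group == "patient_HS"
  if (any(pat & !demographics$lateralization %in% c("left", "right", "bilateral"))) {
    abort_aidhs("HS patients must have lateralization left, right or bilateral",
                "aidhs_validation_error")
  }
  if (any(!pat & demographics$lateralization != "none")) {
    abort_aidhs("lateralization must be 'none' for non-patients",
                "aidhs_validation_error")
  }
  invisible(demographics)
}

validate_cohort <- function(cohort) {
  validate_demographics(cohort$demographics)
  validate_surface(cohort$surface)
  nv <- n_vertices(cohort$surface)
  ids <- cohort$demographics$subject_id

  problems <- character()
  for (sid in ids) {
    m <- cohort$metrics[[sid]]
    if (is.null(m) || !all(c("left", "right") %in% names(m))) {
      problems <- c(problems, sprintf("%s: missing vertex metrics", sid))
      next
    }
    for (h in c("left", "right")) {
      mat <- m[[h]]
      if (nrow(mat) != nv) {
        abort_aidhs(
          sprintf("subject %s %s hemisphere: %d vertex values but the surface has %d vertices",
                  sid, h, nrow(mat), nv),
          "aidhs_format_error"
        )
      }
      if (!all(surface_features() %in% colnames(mat))) {
        problems <- c(problems, sprintf("%s (%s): missing metric feature", sid, h))
      }
    }
    vol <- cohort$volumes[cohort$volumes$subject_id == sid, ]
    if (!all(c("left", "right") %in% vol$hemisphere)) {
      problems <- c(problems, sprintf("%s: missing volume record", sid))
    }
    if (!sid %in% cohort$qc$subject_id) {
      problems <- c(problems, sprintf("%s: missing QC record", sid))
    }
  }
  if (length(problems) > 0) {
    abort_aidhs(
      paste0("cohort has incomplete records:\n",
             paste("-", problems, collapse = "\n")),
      "aidhs_validation_error"
    )
  }
  invisible(cohort)
}

#' Write a cohort to disk
#'
#' Persists a cohort as plain-text files: `demographics.csv`, `volumes.csv`,
#' `qc.csv`, the shared surface as GIFTI (`surface.surf.gii` +
#' `surface_ap.shape.gii`), and vertex metrics in one of two dialects: a
#' single wide table (`metrics.csv`: `subject_id`, `hemisphere`, `feature`,
#' `V1`..`Vn`) or one GIFTI metric file per subject/hemisphere/feature under
#' `metrics/`.
#'
#' @param cohort an [aidhs_cohort()].
#' @param dir output directory (created if needed).
#' @param metric_format `"table"` (default) or `"gifti"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, metric_format = c("table", "gifti")) {
  metric_format <- match.arg(metric_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$demographics, file.path(dir, "demographics.csv"))
  readr::write_csv(cohort$volumes, file.path(dir, "volumes.csv"))
  readr::write_csv(cohort$qc, file.path(dir, "qc.csv"))
  write_gifti_surface(cohort$surface, file.path(dir, "surface.surf.gii"),
                      file.path(dir, "surface_ap.shape.gii"))

  ids <- cohort$demographics$subject_id
  if (metric_format == "table") {
    rows <- list()
    for (sid in ids) {
      for (h in c("left", "right")) {
        mat <- cohort$metrics[[sid]][[h]]
        for (f in surface_features()) {
          rows[[length(rows) + 1L]] <- c(sid, h, f, as.character(mat[, f]))
        }
      }
    }
    nv <- n_vertices(cohort$surface)
    tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(tab) <- c("subject_id", "hemisphere", "feature", paste0("V", seq_len(nv)))
    for (k in seq_len(nv)) tab[[k + 3L]] <- as.numeric(tab[[k + 3L]])
    readr::write_csv(tibble::as_tibble(tab), file.path(dir, "metrics.csv"))
  } else {
    mdir <- file.path(dir, "metrics")
    dir.create(mdir, showWarnings = FALSE)
    for (sid in ids) {
      for (h in c("left", "right")) {
        mat <- cohort$metrics[[sid]][[h]]
        for (f in surface_features()) {
          write_gifti_metric(mat[, f],
                             file.path(mdir, sprintf("%s_%s_%s.shape.gii", sid, h, f)))
        }
      }
    }
  }
  invisible(dir)
}

#' Load a cohort from disk
#'
#' Reads the layout written by [write_cohort()], auto-detecting the metric
#' dialect. Subjects with unresolvable metric files are reported in the
#' error, not silently dropped.
#'
#' @param demographics_path path to the demographics CSV.
#' @param data_dir directory holding the remaining files (defaults to the
#'   demographics file's directory).
#' @return an [aidhs_cohort()].
#' @export
load_cohort <- function(demographics_path, data_dir = dirname(demographics_path)) {
  demographics <- readr::read_csv(demographics_path, show_col_types = FALSE,
                                  progress = FALSE)
  validate_demographics(demographics)
  surface <- read_gifti_surface(file.path(data_dir, "surface.surf.gii"),
                                file.path(data_dir, "surface_ap.shape.gii"))
  volumes <- readr::read_csv(file.path(data_dir, "volumes.csv"),
                             show_col_types = FALSE, progress = FALSE)
  qc <- readr::read_csv(file.path(data_dir, "qc.csv"),
                        show_col_types = FALSE, progress = FALSE)
  nv <- n_vertices(surface)
  ids <- demographics$subject_id
  metrics <- vector("list", length(ids))
  names(metrics) <- ids

  table_path <- file.path(data_dir, "metrics.csv")
  if (file.exists(table_path)) {
    tab <- readr::read_csv(table_path, show_col_types = FALSE, progress = FALSE)
    if (ncol(tab) - 3L != nv) {
      abort_aidhs(sprintf("metrics table has %d vertex columns but the surface has %d vertices",
                          ncol(tab) - 3L, nv), "aidhs_format_error")
    }
    vals <- as.matrix(tab[, -(1:3)])
    key <- paste(tab$subject_id, tab$hemisphere, sep = "\r")
    for (sid in ids) {
      mats <- list()
      for (h in c("left", "right")) {
        sel <- which(key == paste(sid, h, sep = "\r"))
        mat <- matrix(NA_real_, nrow = nv, ncol = length(surface_features()),
                      dimnames = list(NULL, surface_features()))
        for (r in sel) mat[, tab$feature[r]] <- vals[r, ]
        mats[[h]] <- mat
      }
      metrics[[sid]] <- mats
    }
  } else {
    mdir <- file.path(data_dir, "metrics")
    missing_files <- character()
    for (sid in ids) {
      mats <- list()
      for (h in c("left", "right")) {
        mat <- matrix(NA_real_, nrow = nv, ncol = length(surface_features()),
                      dimnames = list(NULL, surface_features()))
        for (f in surface_features()) {
          p <- file.path(mdir, sprintf("%s_%s_%s.shape.gii", sid, h, f))
          if (!file.exists(p)) {
            missing_files <- c(missing_files, basename(p))
            next
          }
          v <- read_gifti_metric(p)
          if (length(v) != nv) {
            abort_aidhs(sprintf("%s: %d vertex values but the surface has %d vertices",
                                basename(p), length(v), nv), "aidhs_format_error")
          }
          mat[, f] <- v
        }
        mats[[h]] <- mat
      }
      metrics[[sid]] <- mats
    }
    if (length(missing_files) > 0) {
      abort_aidhs(paste0("missing metric file(s):\n",
                         paste("-", missing_files, collapse = "\n")),
                  "aidhs_validation_error")
    }
  }
  aidhs_cohort(demographics, surface, metrics, volumes, qc)
}

#' Segmentation quality-control gate
#'
#' Flags subjects whose worse-hemisphere Dice overlap falls strictly below
#' the threshold. The upstream tool's guideline is manual review below 0.7;
#' here flagged subjects are excluded automatically unless listed in
#' `override`.
#'
#' @param cohort an [aidhs_cohort()].
#' @param dice_threshold exclusion threshold on `min(dice_left, dice_right)`;
#'   strictly-below comparisons, so a score of exactly 0.7 is retained.
#' @param override character vector of subject ids to retain despite a
#'   failing score (stands in for the manual visual inspection).
#' @return list with `retained` (an [aidhs_cohort()]) and `excluded`
#'   (tibble `subject_id`, `dice_left`, `dice_right`, `reason`).
#' @export
qc_filter <- function(cohort, dice_threshold = 0.7, override = character()) {
  qc <- cohort$qc
  min_dice <- pmin(qc$dice_left, qc$dice_right)
  fail <- min_dice < dice_threshold & !(qc$subject_id %in% override)
  excluded <- tibble::tibble(
    subject_id = qc$subject_id[fail],
    dice_left = qc$dice_left[fail],
    dice_right = qc$dice_right[fail],
    reason = sprintf("min Dice %.3f below threshold %.3f",
                     min_dice[fail], dice_threshold)
  )
  list(retained = subset_cohort(cohort, setdiff(qc$subject_id, excluded$subject_id)),
       excluded = excluded)
}

#' Subset a cohort by subject id
#' @param cohort an [aidhs_cohort()].
#' @param subject_ids ids to keep.
#' @return an [aidhs_cohort()] restricted to `subject_ids`.
#' @export
subset_cohort <- function(cohort, subject_ids) {
  keep <- cohort$demographics$subject_id %in% subject_ids
  aidhs_cohort(
    demographics = cohort$demographics[keep, ],
    surface = cohort$surface,
    metrics = cohort$metrics[cohort$demographics$subject_id[keep]],
    volumes = cohort$volumes[cohort$volumes$subject_id %in% subject_ids, ],
    qc = cohort$qc[cohort$qc$subject_id %in% subject_ids, ]
  )
}
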