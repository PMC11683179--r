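#' Build an individualized patient report
#'
#' Combines, for one subject: the segmentation QC scores; the placement of
#' both hippocampi on the normative growth charts (value, percentile score
#' and the 5/25/75/95 centile bands at the subject's age and sex); the
#' normalized feature asymmetries against the left/right abnormality
#' thresholds; and the ensemble classifier scores with the detection and
#' lateralization decisions. The report is a pure function of its inputs.
#'
#' @param model an [aidhs_train()] (or [aidhs_load_model()]) model.
#' @param cohort the [aidhs_cohort()] containing the subject.
#' @param subject_id subject to report on.
#' @param predictions optional precomputed [aidhs_predict()] output for the
#'   cohort (computed on demand otherwise).
#' @return object of class `aidhs_report` (nested plain lists; see
#'   [render_report()]).
#' @export
build_report <- function(model, cohort, subject_id, predictions = NULL) {
  for (comp in c("folds", "control_stats", "normative", "thresholds")) {
    if (is.null(model[[comp]])) {
      abort_aidhs(sprintf("model is missing component '%s'", comp),
                  "aidhs_validation_error")
    }
  }
  demo <- cohort$demographics
  if (!subject_id %in% demo$subject_id) {
    abort_aidhs(sprintf("subject %s not in cohort", subject_id),
                "aidhs_validation_error")
  }
  drow <- demo[demo$subject_id == subject_id, ]
  qc <- cohort$qc[cohort$qc$subject_id == subject_id, ]
  dice_thr <- model$settings$dice_threshold %||% 0.7

  if (is.null(predictions)) {
    predictions <- aidhs_predict(model, cohort, apply_qc = FALSE)
  }
  prow <- predictions[predictions$subject_id == subject_id, ]
  if (nrow(prow) != 1) {
    abort_aidhs("no ensemble prediction available for subject", "aidhs_validation_error")
  }

  # per-hemisphere harmonized features for chart placement
  feats <- preprocess_cohort(subset_cohort(cohort, subject_id),
                             n_sd = model$settings$n_sd %||% 5,
                             fwhm_mm = model$settings$fwhm_mm %||% 1,
                             trim_frac = model$settings$trim_frac %||% 0.01)
  harm <- if (isTRUE(model$settings$harmonize) && !is.null(model$combat) &&
              drow$site_id %in% model$combat$sites) {
    apply_combat(model$combat, feats, drow)
  } else {
    skip_combat(feats)
  }
  asym <- compute_asymmetry(harm)
  norm <- normalize_asymmetry(asym, model$control_stats)

  age_grid <- seq(
    min(vapply(model$normative$fits, function(f) f$age_range[1], numeric(1))),
    max(vapply(model$normative$fits, function(f) f$age_range[2], numeric(1))),
    length.out = 60
  )
  normative_sec <- list()
  for (f in aidhs_features()) {
    bands <- lapply(c(5, 25, 50, 75, 95), function(p) {
      suppressWarnings(centile_curve(model$normative, f, drow$sex, p, age_grid)$value)
    })
    names(bands) <- c("p5", "p25", "p50", "p75", "p95")
    hemi <- lapply(c("left", "right"), function(h) {
      val <- harm[[f]][harm$hemisphere == h]
      list(value = val,
           percentile = percentile_score(model$normative, f, val,
                                         drow$age_years, drow$sex))
    })
    names(hemi) <- c("left", "right")
    normative_sec[[f]] <- c(hemi, list(bands = c(list(age = age_grid), bands)))
  }

  thr <- model$thresholds
  asym_sec <- list()
  for (f in aidhs_features()) {
    z <- norm[[f]]
    tl <- thr[thr$feature == f & thr$side == "left", ]
    tr <- thr[thr$feature == f & thr$side == "right", ]
    exceeds <- function(row) {
      if (nrow(row) == 0 || is.na(row$threshold) || is.na(row$slope)) return(FALSE)
      if (row$slope > 0) z > row$threshold else z < row$threshold
    }
    flag <- if (exceeds(tl) && exceeds(tr)) "both"
            else if (exceeds(tl)) "left" else if (exceeds(tr)) "right" else "none"
    asym_sec[[f]] <- list(normalized = z,
                          threshold_left = tl$threshold %||% NA_real_,
                          threshold_right = tr$threshold %||% NA_real_,
                          flag = flag)
  }

  structure(list(
    subject_id = subject_id,
    demographics = list(age_years = drow$age_years, sex = drow$sex,
                        site_id = drow$site_id, group = drow$group),
    qc = list(dice_left = qc$dice_left, dice_right = qc$dice_right,
              threshold = dice_thr,
              passed = min(qc$dice_left, qc$dice_right) >= dice_thr),
    normative = normative_sec,
    asymmetry = asym_sec,
    classifier = list(s_lhs_pct = round(100 * prow$s_lhs, 1),
                      s_rhs_pct = round(100 * prow$s_rhs, 1),
                      s_nohs_pct = round(100 * prow$s_nohs, 1),
                      s_lhs = prow$s_lhs, s_rhs = prow$s_rhs,
                      s_nohs = prow$s_nohs,
                      detection = prow$detection,
                      lateralization = prow$lateralization),
    version = "1"
  ), class = "aidhs_report")
}

#' @export
print.aidhs_report <- function(x, ...) {
  cat(sprintf("<aidhs_report> %s: %s (lateralization %s); scores L %.1f%% / R %.1f%% / none %.1f%%\n",
              x$subject_id, x$classifier$detection, x$classifier$lateralization,
              x$classifier$s_lhs_pct, x$classifier$s_rhs_pct, x$classifier$s_nohs_pct))
  invisible(x)
}

report_to_json <- function(report) {
  jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = I(17),
                   pretty = TRUE, na = "null", null = "null")
}

#' @rdname render_report
#' @param path JSON file written by `render_report(..., format = "json")`.
#' @export
report_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  structure(x, class = "aidhs_report")
}

svg_chart <- function(xs, series, points = NULL, width = 320, height = 180,
                      class = "chart") {
  all_y <- c(unlist(series), vapply(points, `[[`, numeric(1), "y"))
  ylim <- range(all_y)
  pad <- 0.08 * diff(ylim) + 1e-12
  ylim <- ylim + c(-pad, pad)
  xlim <- range(xs)
  px <- function(x) 35 + (x - xlim[1]) / diff(xlim) * (width - 45)
  py <- function(y) height - 20 - (y - ylim[1]) / diff(ylim) * (height - 35)
  poly <- function(upper, lower, fill) {
    pts <- paste(c(paste(px(xs), py(upper), sep = ","),
                   paste(rev(px(xs)), py(rev(lower)), sep = ",")), collapse = " ")
    sprintf('<polygon points="%s" fill="%s" stroke="none"/>', pts, fill)
  }
  line <- function(ys, col) {
    sprintf('<polyline points="%s" fill="none" stroke="%s" stroke-width="1"/>',
            paste(paste(px(xs), py(ys), sep = ","), collapse = " "), col)
  }
  body <- c(
    poly(series$p95, series$p5, "#cdebc9"),
    poly(series$p75, series$p25, "#8fcc8a"),
    line(series$p50, "#3a7d3a")
  )
  for (pt in points) {
    body <- c(body, sprintf(
      '<circle cx="%.1f" cy="%.1f" r="4" fill="%s"><title>%s</title></circle>',
      px(pt$x), py(pt$y), pt$col, pt$label))
  }
  sprintf('<svg class="%s" width="%d" height="%d" xmlns="http://www.w3.org/2000/svg">%s</svg>',
          class, width, height, paste(body, collapse = ""))
}

svg_asym_bar <- function(z, thr_left, thr_right, width = 320, height = 48,
                         class = "asym-bar") {
  lim <- max(4, abs(z) * 1.2, abs(thr_left %||% 0), abs(thr_right %||% 0)) * 1.1
  px <- function(x) width / 2 + x / lim * (width / 2 - 10)
  seg <- function(x, col, dash = "") {
    if (is.null(x) || is.na(x)) return("")
    sprintf('<line x1="%.1f" y1="6" x2="%.1f" y2="%d" stroke="%s" stroke-width="1.5"%s/>',
            px(x), px(x), height - 6, col,
            if (nzchar(dash)) sprintf(' stroke-dasharray="%s"', dash) else "")
  }
  paste0(
    sprintf('<svg class="%s" width="%d" height="%d" xmlns="http://www.w3.org/2000/svg">',
            class, width, height),
    sprintf('<line x1="10" y1="%d" x2="%d" y2="%d" stroke="#999"/>',
            height %/% 2, width - 10, height %/% 2),
    seg(0, "#bbb", "2,2"),
    seg(thr_left, "#4a66d0", "4,2"), seg(thr_right, "#d05a4a", "4,2"),
    sprintf('<rect x="%.1f" y="%d" width="%.1f" height="10" fill="#555"/>',
            min(px(0), px(z)), height %/% 2 - 5, abs(px(z) - px(0))),
    "</svg>")
}

report_html <- function(report) {
  r <- report
  qc_note <- if (isTRUE(r$qc$passed)) "pass" else
    sprintf("BELOW THRESHOLD %.2f - visual inspection required", r$qc$threshold)
  charts <- vapply(aidhs_features(), function(f) {
    sec <- r$normative[[f]]
    series <- sec$bands[c("p5", "p25", "p50", "p75", "p95")]
    pts <- list(
      list(x = r$demographics$age_years, y = sec$left$value, col = "#4a66d0",
           label = sprintf("left: %.4g (centile %.1f)", sec$left$value, sec$left$percentile)),
      list(x = r$demographics$age_years, y = sec$right$value, col = "#d05a4a",
           label = sprintf("right: %.4g (centile %.1f)", sec$right$value, sec$right$percentile))
    )
    paste0("<div class='feature-panel'><h4>", f, "</h4>",
           svg_chart(sec$bands$age, series, pts, class = "feature-chart"),
           sprintf("<p>left centile %.1f / right centile %.1f</p>",
                   sec$left$percentile, sec$right$percentile),
           "</div>")
  }, character(1))
  bars <- vapply(aidhs_features(), function(f) {
    a <- r$asymmetry[[f]]
    paste0("<div class='asym-panel'><h4>", f, "</h4>",
           svg_asym_bar(a$normalized, a$threshold_left, a$threshold_right),
           sprintf("<p>z = %.2f; flag: %s</p>", a$normalized, a$flag), "</div>")
  }, character(1))
  score_bar <- function(lbl, pct, col) {
    sprintf("<div class='score-bar'><span>%s</span><div style='width:%.1f%%;background:%s'>&nbsp;</div><span>%.1f%%</span></div>",
            lbl, pct, col, pct)
  }
  paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'><title>", r$subject_id,
    " hippocampal report</title><style>body{font-family:sans-serif;max-width:760px;margin:auto}",
    ".feature-panel,.asym-panel{display:inline-block;margin:6px}",
    ".score-bar div{display:inline-block;height:14px}</style></head><body>",
    "<h1>Hippocampal report: ", r$subject_id, "</h1>",
    sprintf("<p>Age %.1f y, sex %s, site %s</p>", r$demographics$age_years,
            r$demographics$sex, r$demographics$site_id),
    "<h2>Segmentation quality</h2>",
    sprintf("<p>Dice left %.3f, right %.3f - %s</p>", r$qc$dice_left,
            r$qc$dice_right, qc_note),
    "<h2>Normative growth charts</h2>", paste(charts, collapse = ""),
    "<h2>Feature asymmetries vs abnormality thresholds</h2>",
    paste(bars, collapse = ""),
    "<h2>Classifier</h2>",
    score_bar("left HS", r$classifier$s_lhs_pct, "#4a66d0"),
    score_bar("right HS", r$classifier$s_rhs_pct, "#d05a4a"),
    score_bar("no HS", r$classifier$s_nohs_pct, "#999"),
    sprintf("<p>Detection: <b>%s</b>; lateralization: <b>%s</b></p>",
            r$classifier$detection, r$classifier$lateralization),
    "</body></html>")
}

#' Render a patient report
#'
#' Renders the machine-readable report to a JSON sidecar or a human-readable
#' HTML page (centile-band charts per feature, asymmetry bars against the
#' abnormality thresholds, classifier score bars). Rendering is
#' deterministic: the same report yields byte-identical output.
#'
#' @param report an [build_report()] report.
#' @param format `"json"` or `"html"`.
#' @param path optional output file; when `NULL` the document is returned as
#'   a string.
#' @return the rendered document (invisibly when `path` is given).
#' @export
render_report <- function(report, format = c("json", "html"), path = NULL) {
  format <- match.arg(format)
  doc <- switch(format, json = as.character(report_to_json(report)),
                html = report_html(report))
  if (!is.null(path)) {
    writeLines(doc, path, useBytes = TRUE)
    return(invisible(doc))
  }
  doc
}

#' Write the report pair for a subject
#'
#' Convenience wrapper producing `<subject_id>_aidhs_report.json` and
#' `<subject_id>_aidhs_report.html` in `dir`.
#'
#' @inheritParams build_report
#' @param dir output directory.
#' @return named character vector of the two paths, invisibly.
#' @export
write_report <- function(model, cohort, subject_id, dir = ".",
                         predictions = NULL) {
  report <- build_report(model, cohort, subject_id, predictions = predictions)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    json = file.path(dir, paste0(subject_id, "_aidhs_report.json")),
    html = file.path(dir, paste0(subject_id, "_aidhs_report.html"))
  )
  render_report(report, "json", paths["json"])
  render_report(report, "html", paths["html"])
  invisible(paths)
}
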