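# Cohort orchestration: per-scan-pair analysis (segment -> aeration ->
# register -> warp -> SVg/Delta-SVg -> classify), longitudinal fold-changes
# versus the basal condition, and group-level summary tables.

#' Analyze one inspiratory/expiratory scan pair
#'
#' Runs the full per-scan pipeline: segment both phases (or accept supplied
#' masks), compute aeration morphometrics for both phases, register P02 to
#' P01, warp, build SVg and Delta-SVg maps and, when thresholds are given,
#' classify voxels into ventilation classes. Stage failures are propagated
#' as QC flags (`segmentation-failure`, `registration-failure`) with the
#' affected metrics absent — never silently dropped.
#'
#' @param p01,p02 [ct_volume()]s of the two phases on a common grid.
#' @param config An [analysis_config()].
#' @param thresholds Optional [ventilation_thresholds()]; when absent the
#'   functional metrics are omitted and flagged `thresholds-absent`.
#' @param mask_p01,mask_p02 Optional [lung_labels()]; segmented from the
#'   images when `NULL`. The warped-P02 mask is obtained by warping
#'   `mask_p02` when supplied, else by segmenting the warped P02 image.
#' @param keep_maps Keep the SVg/Delta-SVg maps and field in the report
#'   (needed for threshold calibration).
#' @return An object of class `subject_timepoint_report`.
#' @export
analyze_scan_pair <- function(p01, p02, config = analysis_config(),
                              thresholds = NULL,
                              mask_p01 = NULL, mask_p02 = NULL,
                              keep_maps = FALSE) {
  stop_on_grid_mismatch(p01, p02, "analyze_scan_pair")
  qc <- character(0)
  rep_out <- list(subject_id = p01$subject_id, day = p01$day,
                  aeration = NULL, tidal = NULL, ventilation = NULL,
                  maps = NULL, qc_flags = character(0))
  class(rep_out) <- "subject_timepoint_report"

  seg <- function(ct) segment_lungs(ct, config$segmentation)
  if (is.null(mask_p01))
    mask_p01 <- tryCatch(seg(p01), error = function(e) {
      qc <<- c(qc, "segmentation-failure"); NULL })
  if (is.null(mask_p02) && !is.null(mask_p01))
    mask_p02 <- tryCatch(seg(p02), error = function(e) {
      qc <<- c(qc, "segmentation-failure"); NULL })
  if (is.null(mask_p01) || is.null(mask_p02)) {
    rep_out$qc_flags <- unique(qc)
    return(rep_out)
  }

  bounds <- config$aeration_boundaries_hu
  aer <- do.call(rbind, c(
    lapply(c("whole", "left", "right"), function(r)
      aeration_report(p01, mask_p01, r, bounds, phase = "P01")),
    lapply(c("whole", "left", "right"), function(r)
      aeration_report(p02, mask_p02, r, bounds, phase = "P02"))))
  rep_out$aeration <- aer
  rep_out$tidal <- data.frame(
    region = c("whole", "left", "right"),
    tidal_volume_mm3 = vapply(c("whole", "left", "right"), function(r)
      tidal_volume(mask_p01, mask_p02, r), 0),
    stringsAsFactors = FALSE, row.names = NULL)

  regres <- tryCatch(register_pair(p01, p02, config$registration),
                     error = function(e) {
                       qc <<- c(qc, "registration-failure"); NULL })
  if (is.null(regres)) {
    rep_out$qc_flags <- unique(qc)
    return(rep_out)
  }
  warped_mask <- tryCatch(
    if (!is.null(mask_p02)) warp_volume(mask_p02, regres$field) else seg(regres$warped_p02),
    error = function(e) { qc <<- c(qc, "segmentation-failure"); NULL })
  if (is.null(warped_mask) || !any(warped_mask$labels > 0L)) {
    qc <- c(qc, "registration-failure")
    rep_out$qc_flags <- unique(qc)
    return(rep_out)
  }

  tsv <- config$tissue_specific_volume_ml_per_g
  clip <- config$hu_clip_range
  svg_p01 <- specific_gas_volume(p01, mask_p01, tsv, clip)
  svg_p02 <- specific_gas_volume(regres$warped_p02, warped_mask, tsv, clip)
  dsv <- delta_svg(svg_p01, svg_p02)
  if (keep_maps)
    rep_out$maps <- list(svg_p01 = svg_p01, svg_p02 = svg_p02, delta = dsv,
                         field = regres$field, mask_p01 = mask_p01,
                         warped_mask = warped_mask)

  if (is.null(thresholds)) {
    qc <- c(qc, "thresholds-absent")
  } else {
    vent <- classify_voxels(svg_p01, svg_p02, dsv, thresholds, mask_p01,
                            mixed_class = config$mixed_class)
    rep_out$ventilation <- vent$summary
    if (keep_maps) rep_out$maps$class_map <- vent$class_map
  }
  rep_out$qc_flags <- unique(qc)
  rep_out
}

#' @export
print.subject_timepoint_report <- function(x, ...) {
  cat(sprintf("<subject_timepoint_report %s day %s; QC: %s>\n",
              ifelse(is.na(x$subject_id), "?", x$subject_id),
              ifelse(is.na(x$day), "?", x$day),
              if (length(x$qc_flags)) paste(x$qc_flags, collapse = ", ") else "clean"))
  invisible(x)
}

fold_metrics_from_report <- function(rep) {
  # expiratory-phase morphology (the longitudinal readouts are derived from
  # end-expiratory images) + tidal volume + functional classes
  out <- list()
  if (!is.null(rep$aeration)) {
    a2 <- rep$aeration[rep$aeration$phase == "P02", ]
    for (i in seq_len(nrow(a2))) {
      r <- a2[i, ]
      for (m in c("volume_mm3", "mla_hu", "pct_normo", "pct_hypo", "pct_non",
                  "pct_gas", "gas_volume_mm3", "tissue_volume_mm3"))
        out[[length(out) + 1L]] <- data.frame(region = r$region, metric = m,
                                              value = r[[m]])
    }
  }
  if (!is.null(rep$tidal)) {
    for (i in seq_len(nrow(rep$tidal)))
      out[[length(out) + 1L]] <- data.frame(region = rep$tidal$region[i],
                                            metric = "tidal_volume_mm3",
                                            value = rep$tidal$tidal_volume_mm3[i])
  }
  if (!is.null(rep$ventilation)) {
    for (i in seq_len(nrow(rep$ventilation))) {
      r <- rep$ventilation[i, ]
      for (m in c("pct_normal_vent", "pct_low_vent", "pct_fibrosis"))
        out[[length(out) + 1L]] <- data.frame(region = r$region, metric = m,
                                              value = r[[m]])
    }
  }
  do.call(rbind, out)
}

# metrics reported as raw values (baseline near zero makes ratios unstable)
RAW_METRICS <- "pct_fibrosis"

#' Fold-change versus the basal condition
#'
#' For one subject's longitudinal reports, expresses every metric and
#' region as `value(day) / value(day 0)`. Fibrosis percentages are emitted
#' as raw values with `fold_change = NA`, because their baseline is close
#' to 0% and the ratio is unstable. Baselines equal to zero also yield
#' `NA` fold-changes.
#'
#' @param reports List of `subject_timepoint_report`s for one subject,
#'   including a day-0 report.
#' @param subject_id,group Identifiers copied into the rows.
#' @return A long data.frame: subject_id, group, day, region, metric,
#'   value, baseline_value, fold_change.
#' @export
fold_change_vs_baseline <- function(reports, subject_id = NA_character_,
                                    group = NA_character_) {
  days <- vapply(reports, function(r) as.integer(r$day), 0L)
  if (!0L %in% days)
    stop("fold_change_vs_baseline: subject has no day-0 (basal) report",
         call. = FALSE)
  base <- fold_metrics_from_report(reports[[which(days == 0L)[1]]])
  if (is.null(base)) stop("fold_change_vs_baseline: basal report has no metrics",
                          call. = FALSE)
  rows <- lapply(seq_along(reports), function(i) {
    mt <- fold_metrics_from_report(reports[[i]])
    if (is.null(mt)) return(NULL)
    mt$day <- days[i]
    mt$baseline_value <- base$value[match(paste(mt$region, mt$metric),
                                          paste(base$region, base$metric))]
    mt$fold_change <- ifelse(
      mt$metric %in% RAW_METRICS | mt$baseline_value == 0,
      NA_real_, mt$value / mt$baseline_value)
    mt
  })
  out <- do.call(rbind, rows)
  out$subject_id <- subject_id
  out$group <- group
  out[, c("subject_id", "group", "day", "region", "metric", "value",
          "baseline_value", "fold_change")]
}

#' Group-level summary statistics
#'
#' Mean, standard error of the mean (sd with n-1 denominator over sqrt(n))
#' and count for one metric of one group at one day.
#'
#' @param table A fold-change table from [fold_change_vs_baseline()]
#'   (possibly row-bound over subjects).
#' @param group,day,metric,region Selection.
#' @param value_col `"fold_change"` or `"value"` (raw metrics such as
#'   fibrosis percentages use `"value"`).
#' @param sem_single How to report the SEM of a single subject: `"na"`
#'   (default) or `"zero"`.
#' @return Named list: `mean`, `sem`, `n`.
#' @export
summarize_group <- function(table, group, day, metric, region = "whole",
                            value_col = c("fold_change", "value"),
                            sem_single = c("na", "zero")) {
  value_col <- match.arg(value_col)
  sem_single <- match.arg(sem_single)
  sel <- table$group == group & table$day == day & table$metric == metric &
    table$region == region
  v <- table[[value_col]][sel]
  v <- v[is.finite(v)]
  n <- length(v)
  if (n < 1L) stop("summarize_group: no observations for this selection",
                   call. = FALSE)
  sem <- if (n == 1L) {
    if (sem_single == "zero") 0 else NA_real_
  } else sd(v) / sqrt(n)
  list(mean = mean(v), sem = sem, n = n)
}

#' Run the full cohort pipeline from a manifest
#'
#' Validates the manifest (all referenced files must exist; missing files
#' are listed and the run aborts before any analysis), calibrates the
#' ventilation thresholds on the day-0 scans, analyzes every pair, and
#' writes per-subject report JSONs, a tidy long fold-change CSV and a
#' group-summary CSV. Deterministic given inputs.
#'
#' @param manifest Data.frame or CSV path with columns subject_id, group,
#'   day, p01_path, p02_path and optionally mask_path / mask_p02_path
#'   (used when `use_masks = TRUE`).
#' @param config An [analysis_config()].
#' @param out_dir Output directory.
#' @param use_masks Use manifest-supplied masks instead of segmenting.
#' @param calibration_groups Groups whose day-0 scans calibrate the
#'   thresholds (default all groups: every animal is unchallenged at
#'   day 0).
#' @return List: `reports` (named list), `fold_changes` (data.frame),
#'   `group_summary` (data.frame), `thresholds`.
#' @export
run_cohort <- function(manifest, config = analysis_config(), out_dir,
                       use_masks = TRUE, calibration_groups = NULL) {
  if (is.character(manifest)) manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  needed <- c("subject_id", "group", "day", "p01_path", "p02_path")
  if (!all(needed %in% names(manifest)))
    stop("run_cohort: manifest must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  path_cols <- intersect(c("p01_path", "p02_path", "mask_path", "mask_p02_path"),
                         names(manifest))
  refs <- unlist(manifest[path_cols], use.names = FALSE)
  missing <- refs[!file.exists(refs)]
  if (length(missing))
    stop("run_cohort: manifest references missing files:\n  ",
         paste(unique(missing), collapse = "\n  "), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "reports"), showWarnings = FALSE)

  load_row <- function(row) {
    p01 <- read_volume(row$p01_path, phase = "P01",
                       subject_id = row$subject_id, day = row$day)
    p02 <- read_volume(row$p02_path, phase = "P02",
                       subject_id = row$subject_id, day = row$day)
    m1 <- m2 <- NULL
    if (use_masks && "mask_path" %in% names(row) && nzchar(row$mask_path))
      m1 <- read_labels(row$mask_path)
    if (use_masks && "mask_p02_path" %in% names(row) && nzchar(row$mask_p02_path))
      m2 <- read_labels(row$mask_p02_path)
    list(p01 = p01, p02 = p02, mask_p01 = m1, mask_p02 = m2)
  }

  # pass 1: day-0 scans, keeping maps for calibration
  base_rows <- which(manifest$day == 0)
  base_reports <- list()
  for (i in base_rows) {
    row <- manifest[i, ]
    dat <- load_row(row)
    base_reports[[row$subject_id]] <- analyze_scan_pair(
      dat$p01, dat$p02, config, thresholds = NULL,
      mask_p01 = dat$mask_p01, mask_p02 = dat$mask_p02, keep_maps = TRUE)
  }
  calib_subjects <- names(base_reports)
  if (!is.null(calibration_groups)) {
    keep <- manifest$subject_id[manifest$day == 0 &
                                  manifest$group %in% calibration_groups]
    calib_subjects <- intersect(calib_subjects, keep)
  }
  basal_pairs <- Filter(Negate(is.null),
                        lapply(base_reports[calib_subjects], `[[`, "maps"))
  if (!length(basal_pairs))
    stop("run_cohort: no usable day-0 scans for threshold calibration",
         call. = FALSE)
  thresholds <- calibrate_thresholds(basal_pairs,
                                     percentiles = config$calibration_percentiles,
                                     pooled = config$calibration_pooled)

  # classify the baselines with the calibrated thresholds, then the rest
  reports <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    key <- sprintf("%s_d%02d", row$subject_id, row$day)
    if (row$day == 0 && !is.null(base_reports[[row$subject_id]]$maps)) {
      rep0 <- base_reports[[row$subject_id]]
      m <- rep0$maps
      vent <- classify_voxels(m$svg_p01, m$svg_p02, m$delta, thresholds,
                              m$mask_p01, mixed_class = config$mixed_class)
      rep0$ventilation <- vent$summary
      rep0$qc_flags <- setdiff(rep0$qc_flags, "thresholds-absent")
      rep0$maps <- NULL
      reports[[key]] <- rep0
    } else if (row$day == 0) {
      rep0 <- base_reports[[row$subject_id]]
      rep0$maps <- NULL
      reports[[key]] <- rep0
    } else {
      dat <- load_row(row)
      reports[[key]] <- analyze_scan_pair(
        dat$p01, dat$p02, config, thresholds = thresholds,
        mask_p01 = dat$mask_p01, mask_p02 = dat$mask_p02)
    }
    rpt <- reports[[key]]
    jsonlite::write_json(
      list(subject_id = row$subject_id, group = row$group, day = row$day,
           qc_flags = rpt$qc_flags, aeration = rpt$aeration,
           tidal = rpt$tidal, ventilation = rpt$ventilation),
      file.path(out_dir, "reports", paste0(key, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  }

  # fold changes per subject
  fc <- list()
  for (sid in unique(manifest$subject_id)) {
    sel <- manifest$subject_id == sid
    keys <- sprintf("%s_d%02d", sid, manifest$day[sel])
    subj_reports <- reports[keys]
    days <- manifest$day[sel]
    grp <- manifest$group[sel][1]
    for (k in seq_along(subj_reports)) subj_reports[[k]]$day <- days[k]
    if (!0 %in% days || is.null(subj_reports[[which(days == 0)[1]]]$aeration)) {
      warning("run_cohort: subject ", sid,
              " lacks a usable day-0 report; excluded from fold-change table",
              call. = FALSE)
      next
    }
    usable <- !vapply(subj_reports, function(r) is.null(r$aeration), TRUE)
    fc[[sid]] <- fold_change_vs_baseline(subj_reports[usable],
                                         subject_id = sid, group = grp)
  }
  fold_changes <- do.call(rbind, fc)
  rownames(fold_changes) <- NULL
  write.csv(fold_changes, file.path(out_dir, "fold_changes.csv"),
            row.names = FALSE)

  # group summaries over every (group, day, region, metric)
  combos <- unique(fold_changes[, c("group", "day", "region", "metric")])
  gs <- lapply(seq_len(nrow(combos)), function(i) {
    cb <- combos[i, ]
    vc <- if (cb$metric %in% RAW_METRICS) "value" else "fold_change"
    s <- tryCatch(summarize_group(fold_changes, cb$group, cb$day, cb$metric,
                                  cb$region, value_col = vc),
                  error = function(e) NULL)
    if (is.null(s)) return(NULL)
    data.frame(group = cb$group, day = cb$day, region = cb$region,
               metric = cb$metric, statistic = vc,
               mean = s$mean, sem = s$sem, n = s$n, stringsAsFactors = FALSE)
  })
  group_summary <- do.call(rbind, gs)
  write.csv(group_summary, file.path(out_dir, "group_summary.csv"),
            row.names = FALSE)

  list(reports = reports, fold_changes = fold_changes,
       group_summary = group_summary, thresholds = thresholds)
}
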