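#' Analysis configuration
#'
#' Bundles every tunable constant of the pipeline with its published or
#' declared default. Aeration boundaries follow the preclinical HU ranges:
#' normo-aerated `[-860, -435]`, hypo-aerated `(-435, -121)`, non-aerated
#' `[-121, 121]`; voxels outside all three (hyper-aerated below -860 HU or
#' above 121 HU) are reported as "other" rather than silently dropped.
#'
#' @param aeration_boundaries_hu Strictly increasing numeric vector
#'   `c(normo_lo, normo_hi, non_lo, non_hi)`, default
#'   `c(-860, -435, -121, 121)`.
#' @param tissue_specific_volume_ml_per_g Specific volume of lung tissue,
#'   default `1/1.065` = 0.939 ml/g.
#' @param hu_clip_range HU clipping applied before the `1000/(HU+1000)`
#'   specific-volume transform, which diverges at -1000 HU; default
#'   `c(-990, 1000)` bounds SVg at about 99 ml/g.
#' @param calibration_percentiles Percentiles `c(alpha_I, alpha_E, beta)`
#'   used to calibrate the ventilation thresholds on a basal cohort,
#'   default `c(5, 5, 25)`.
#' @param calibration_pooled If `TRUE`, thresholds are percentiles of the
#'   pooled basal voxel distribution; default `FALSE` = per-animal
#'   percentiles averaged across the cohort.
#' @param mixed_class How to report voxels with reduced ventilation that
#'   meet only one of the two per-phase SVg conditions: `"low"` (default)
#'   folds them into Low vent, `"separate"` reports them as a fourth class.
#' @param segmentation List: `threshold_hu` (air threshold, default -200)
#'   and `closing_radius_voxels` (default 2).
#' @param registration A [registration_params()] list.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(aeration_boundaries_hu = c(-860, -435, -121, 121),
                            tissue_specific_volume_ml_per_g = 1 / 1.065,
                            hu_clip_range = c(-990, 1000),
                            calibration_percentiles = c(5, 5, 25),
                            calibration_pooled = FALSE,
                            mixed_class = c("low", "separate"),
                            segmentation = list(threshold_hu = -200,
                                                closing_radius_voxels = 2),
                            registration = registration_params()) {
  if (is.unsorted(aeration_boundaries_hu, strictly = TRUE))
    stop("analysis_config: aeration boundaries must be strictly increasing",
         call. = FALSE)
  if (length(aeration_boundaries_hu) != 4L)
    stop("analysis_config: need 4 aeration boundaries", call. = FALSE)
  if (tissue_specific_volume_ml_per_g <= 0)
    stop("analysis_config: tissue specific volume must be > 0", call. = FALSE)
  if (any(calibration_percentiles <= 0) || any(calibration_percentiles >= 100))
    stop("analysis_config: calibration percentiles must lie in (0, 100)",
         call. = FALSE)
  structure(list(
    aeration_boundaries_hu = as.numeric(aeration_boundaries_hu),
    tissue_specific_volume_ml_per_g = tissue_specific_volume_ml_per_g,
    hu_clip_range = as.numeric(hu_clip_range),
    calibration_percentiles = as.numeric(calibration_percentiles),
    calibration_pooled = isTRUE(calibration_pooled),
    mixed_class = match.arg(mixed_class),
    segmentation = segmentation,
    registration = registration
  ), class = "analysis_config")
}

#' Write / read an analysis configuration (JSON)
#'
#' The configuration round-trips losslessly through JSON; every constant in
#' the pipeline (aeration boundaries, tissue specific volume, percentiles,
#' registration parameters) is overridable from the file.
#'
#' @param config An [analysis_config()].
#' @param path JSON file path.
#' @return `write_config`: `path` invisibly; `read_config`: the config.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  reg <- do.call(registration_params, raw$registration %||% list())
  analysis_config(
    aeration_boundaries_hu = raw$aeration_boundaries_hu,
    tissue_specific_volume_ml_per_g = raw$tissue_specific_volume_ml_per_g,
    hu_clip_range = raw$hu_clip_range,
    calibration_percentiles = raw$calibration_percentiles,
    calibration_pooled = raw$calibration_pooled,
    mixed_class = raw$mixed_class,
    segmentation = as.list(raw$segmentation),
    registration = reg
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
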