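# Specific-gas-volume ventilation mapping: per-voxel SVg maps for each
# phase, voxel-wise inspiratory-minus-expiratory difference (Delta-SVg),
# percentile calibration of the (alpha_I, alpha_E, beta) thresholds on a
# basal cohort, and the three-class Normal/Low/Fibrosis voxel classifier.

#' Specific gas volume map
#'
#' Per lung voxel, `SVg = SV_lung - SV_tissue` with
#' `SV_lung (ml/g) = 1000/(HU + 1000)` and the tissue specific volume taken
#' as `1/1.065 = 0.939 ml/g`. HU is clipped (default to `[-990, 1000]`)
#' before the division, which diverges at -1000 HU; the clip bounds SVg at
#' about 99 ml/g. SVg is strictly decreasing in HU and crosses zero near
#' 65 HU (tissue-density voxels carry no gas).
#'
#' @param ct A [ct_volume()] (raw HU; for the expiratory phase this must be
#'   the registration-warped P02 volume on the P01 grid).
#' @param mask A [lung_labels()] on the same grid.
#' @param tissue_sv Tissue specific volume in ml/g (default `1/1.065`).
#' @param hu_clip Length-2 HU clipping range.
#' @return An object of class `svg_map`: `values` (3D array, `NA` outside
#'   the lung), `mask` (logical array), grid descriptors and a `phase` tag.
#' @export
specific_gas_volume <- function(ct, mask, tissue_sv = 1 / 1.065,
                                hu_clip = c(-990, 1000)) {
  stopifnot(tissue_sv > 0)
  stop_on_grid_mismatch(ct, mask, "specific_gas_volume")
  inlung <- mask$labels > 0L
  hu <- pmin(pmax(ct$values, hu_clip[1]), hu_clip[2])
  sv <- array(NA_real_, dim(hu))
  sv[inlung] <- 1000 / (hu[inlung] + 1000) - tissue_sv
  structure(list(values = sv, mask = inlung,
                 spacing_mm = ct$spacing_mm, origin_mm = ct$origin_mm,
                 phase = ct$phase),
            class = "svg_map")
}

#' Delta-SVg ventilation map
#'
#' Voxel-wise `SVg_P01 - SVg_P02` inside the intersection of the two lung
#' masks (the P01 mask and the warped-P02 mask); outside the intersection
#' Delta-SVg is undefined and those voxels are excluded from all
#' classification denominators. Positive values mean the voxel holds more
#' air per gram of tissue at end-inspiration, i.e. it ventilates.
#'
#' @param svg_p01 `svg_map` of the inspiratory volume.
#' @param svg_warped_p02 `svg_map` of the registration-warped expiratory
#'   volume (P01 grid).
#' @return An object of class `delta_svg_map` with `values` and `mask`.
#' @export
delta_svg <- function(svg_p01, svg_warped_p02) {
  if (!identical(dim(svg_p01$values), dim(svg_warped_p02$values)))
    stop("delta_svg: grid mismatch between SVg maps", call. = FALSE)
  both <- svg_p01$mask & svg_warped_p02$mask
  dv <- array(NA_real_, dim(svg_p01$values))
  dv[both] <- svg_p01$values[both] - svg_warped_p02$values[both]
  structure(list(values = dv, mask = both,
                 spacing_mm = svg_p01$spacing_mm,
                 origin_mm = svg_p01$origin_mm),
            class = "delta_svg_map")
}

#' Ventilation classification thresholds
#'
#' The calibrated triple in ml/g: `alpha_I` and `alpha_E` are the 5th
#' percentiles of the basal inspiratory and expiratory SVg distributions,
#' `beta` the 25th percentile of the basal Delta-SVg distribution.
#'
#' @param alpha_I,alpha_E,beta Thresholds in ml/g.
#' @param provenance Free-form description of the calibration cohort and
#'   percentile settings.
#' @return An object of class `ventilation_thresholds`.
#' @export
ventilation_thresholds <- function(alpha_I, alpha_E, beta, provenance = "") {
  stopifnot(is.finite(alpha_I), is.finite(alpha_E), is.finite(beta))
  if (beta <= 0)
    warning("ventilation_thresholds: beta <= 0; basal cohort does not look ",
            "compressive", call. = FALSE)
  structure(list(alpha_I = alpha_I, alpha_E = alpha_E, beta = beta,
                 provenance = provenance),
            class = "ventilation_thresholds")
}

#' @export
print.ventilation_thresholds <- function(x, ...) {
  cat(sprintf("<ventilation_thresholds alpha_I=%.4f alpha_E=%.4f beta=%.4f ml/g>\n",
              x$alpha_I, x$alpha_E, x$beta))
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n")
  invisible(x)
}

#' Calibrate ventilation thresholds on a basal cohort
#'
#' For each baseline (day-0, pre-challenge) animal, computes the 5th
#' percentile of its lung-voxel inspiratory SVg distribution, the 5th
#' percentile of its (warped) expiratory SVg distribution, and the 25th
#' percentile of its Delta-SVg distribution; the thresholds are the means
#' of these per-animal percentiles across the cohort. All percentiles are
#' evaluated over the voxels that enter classification (the mask
#' intersection). With `pooled = TRUE` the percentiles are instead taken on
#' the pooled voxel distribution of the whole cohort (alternative reading
#' of "basal mean distribution"; both are supported, per-animal is the
#' default).
#'
#' @param basal_pairs List; each element a list with components `svg_p01`,
#'   `svg_p02` (`svg_map`s) and `delta` (`delta_svg_map`), as produced by
#'   [analyze_scan_pair()] or assembled manually.
#' @param percentiles Numeric `c(p_alpha_I, p_alpha_E, p_beta)`, default
#'   `c(5, 5, 25)`.
#' @param pooled Pool voxels across animals instead of averaging per-animal
#'   percentiles.
#' @return A [ventilation_thresholds()].
#' @export
calibrate_thresholds <- function(basal_pairs, percentiles = c(5, 5, 25),
                                 pooled = FALSE) {
  if (length(basal_pairs) < 1L)
    stop("calibrate_thresholds: empty basal cohort", call. = FALSE)
  pull <- function(pair) {
    if (is.null(pair$delta))
      stop("calibrate_thresholds: a basal pair lacks a Delta-SVg map",
           call. = FALSE)
    dom <- pair$delta$mask
    list(i = pair$svg_p01$values[dom],
         e = pair$svg_p02$values[dom],
         d = pair$delta$values[dom])
  }
  vox <- lapply(basal_pairs, pull)
  p <- percentiles / 100
  if (pooled) {
    aI <- quantile(unlist(lapply(vox, `[[`, "i")), p[1], names = FALSE)
    aE <- quantile(unlist(lapply(vox, `[[`, "e")), p[2], names = FALSE)
    b  <- quantile(unlist(lapply(vox, `[[`, "d")), p[3], names = FALSE)
  } else {
    aI <- mean(vapply(vox, function(v) quantile(v$i, p[1], names = FALSE), 0))
    aE <- mean(vapply(vox, function(v) quantile(v$e, p[2], names = FALSE), 0))
    b  <- mean(vapply(vox, function(v) quantile(v$d, p[3], names = FALSE), 0))
  }
  ventilation_thresholds(aI, aE, b, provenance = sprintf(
    "%s percentiles (%g, %g, %g) over %d basal animals",
    if (pooled) "pooled-voxel" else "per-animal mean",
    percentiles[1], percentiles[2], percentiles[3], length(basal_pairs)))
}

#' Classify lung voxels into Normal / Low / Fibrosis ventilation classes
#'
#' Three-class functional classification: a voxel is Normal when
#' `Delta-SVg >= beta`; otherwise it is Fibrosis when both `SVg_P01 <
#' alpha_I` and `SVg_P02 < alpha_E` (reduced ventilation due to dense,
#' non-aerated tissue in both phases), and Low otherwise (reduced
#' ventilation not due to fibrosis). Mixed cases — reduced ventilation
#' with exactly one of the two per-phase SVg conditions met — fall to Low
#' by default; `mixed_class = "separate"` reports them as a fourth class.
#' Every voxel of the classification domain receives exactly one class.
#'
#' @param svg_p01,svg_warped_p02 `svg_map`s on the P01 grid.
#' @param delta The `delta_svg_map` of the pair.
#' @param thresholds A [ventilation_thresholds()].
#' @param mask A [lung_labels()] used for per-region summaries.
#' @param mixed_class `"low"` (default) or `"separate"`.
#' @return An object of class `ventilation_report`: `class_map` (integer 3D
#'   array, 0 outside, 1 Normal, 2 Low, 3 Fibrosis, 4 Mixed when separate)
#'   and `summary`, a data.frame of per-region percentages summing to 100.
#' @export
classify_voxels <- function(svg_p01, svg_warped_p02, delta, thresholds, mask,
                            mixed_class = c("low", "separate")) {
  mixed_class <- match.arg(mixed_class)
  if (!inherits(thresholds, "ventilation_thresholds"))
    stop("classify_voxels: thresholds must be calibrated ",
         "(a ventilation_thresholds object)", call. = FALSE)
  dom <- delta$mask
  d <- dim(delta$values)
  cls <- array(0L, d)
  normal <- dom & (delta$values >= thresholds$beta)
  reduced <- dom & !normal
  fib <- reduced & (svg_p01$values < thresholds$alpha_I) &
                   (svg_warped_p02$values < thresholds$alpha_E)
  low <- reduced & !fib
  cls[normal] <- 1L
  cls[low] <- 2L
  cls[fib] <- 3L
  if (mixed_class == "separate") {
    mix <- reduced & !fib &
      ((svg_p01$values < thresholds$alpha_I) |
       (svg_warped_p02$values < thresholds$alpha_E))
    cls[mix] <- 4L
  }
  rows <- lapply(c("whole", "left", "right"), function(reg) {
    sel <- region_mask(mask, reg) & dom
    n <- sum(sel)
    if (n == 0L)
      return(data.frame(region = reg, n_voxels = 0L, pct_normal_vent = NA_real_,
                        pct_low_vent = NA_real_, pct_fibrosis = NA_real_,
                        pct_mixed = NA_real_, stringsAsFactors = FALSE))
    data.frame(region = reg, n_voxels = n,
               pct_normal_vent = 100 * sum(cls[sel] == 1L) / n,
               pct_low_vent = 100 * sum(cls[sel] == 2L) / n,
               pct_fibrosis = 100 * sum(cls[sel] == 3L) / n,
               pct_mixed = 100 * sum(cls[sel] == 4L) / n,
               stringsAsFactors = FALSE)
  })
  structure(list(class_map = cls, summary = do.call(rbind, rows),
                 thresholds = thresholds, mixed_class = mixed_class,
                 spacing_mm = delta$spacing_mm),
            class = "ventilation_report")
}
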