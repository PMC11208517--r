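# Morphological biomarkers: per-region lung volume, mean lung attenuation,
# HU aeration compartments, gas/tissue decomposition and tidal volume.

voxel_volume_mm3 <- function(x) prod(grid_of(x)$spacing)

check_region_nonempty <- function(sel, region, where) {
  if (!any(sel))
    stop(where, ": region \"", region, "\" is empty", call. = FALSE)
  invisible(TRUE)
}

#' Mean lung attenuation (MLA)
#'
#' Arithmetic mean HU over the voxels of a lung region.
#'
#' @param ct A [ct_volume()].
#' @param mask A [lung_labels()] on the same grid.
#' @param region `"whole"`, `"left"` or `"right"`.
#' @return Mean HU (scalar).
#' @export
mean_lung_attenuation <- function(ct, mask, region = "whole") {
  stop_on_grid_mismatch(ct, mask, "mean_lung_attenuation")
  sel <- region_mask(mask, region)
  check_region_nonempty(sel, region, "mean_lung_attenuation")
  mean(ct$values[sel])
}

#' Lung volume
#'
#' Voxel count times voxel volume, in mm^3.
#'
#' @inheritParams mean_lung_attenuation
#' @return Volume in mm^3 (0 for an empty region).
#' @export
lung_volume <- function(mask, region = "whole") {
  stopifnot(inherits(mask, "lung_labels"))
  sum(region_mask(mask, region)) * voxel_volume_mm3(mask)
}

#' Aeration compartments
#'
#' Fractions of region voxels falling in the preclinical HU aeration ranges:
#' normo-aerated `[b1, b2]` (closed), hypo-aerated `(b2, b3)` (open),
#' non-aerated `[b3, b4]` (closed), with defaults `b = (-860, -435, -121,
#' 121)`. A voxel at exactly -435 HU is normo-aerated and a voxel at exactly
#' -121 HU is non-aerated (closed brackets). Everything else in the region
#' (hyper-aerated below b1, or above b4) is reported as `pct_other`; the
#' denominator is all region voxels.
#'
#' @inheritParams mean_lung_attenuation
#' @param boundaries_hu Strictly increasing numeric vector of length 4.
#' @return Named numeric: `pct_normo`, `pct_hypo`, `pct_non`, `pct_other`
#'   (percentages summing to 100).
#' @export
aeration_compartments <- function(ct, mask, region = "whole",
                                  boundaries_hu = c(-860, -435, -121, 121)) {
  stop_on_grid_mismatch(ct, mask, "aeration_compartments")
  if (is.unsorted(boundaries_hu, strictly = TRUE) || length(boundaries_hu) != 4L)
    stop("aeration_compartments: boundaries must be 4 strictly increasing values",
         call. = FALSE)
  sel <- region_mask(mask, region)
  check_region_nonempty(sel, region, "aeration_compartments")
  hu <- ct$values[sel]
  b <- boundaries_hu
  n <- length(hu)
  n_normo <- sum(hu >= b[1] & hu <= b[2])
  n_hypo  <- sum(hu >  b[2] & hu <  b[3])
  n_non   <- sum(hu >= b[3] & hu <= b[4])
  c(pct_normo = 100 * n_normo / n,
    pct_hypo  = 100 * n_hypo / n,
    pct_non   = 100 * n_non / n,
    pct_other = 100 * (n - n_normo - n_hypo - n_non) / n)
}

#' Gas/tissue volume decomposition
#'
#' Standard CT densitometry split: per-voxel gas fraction
#' `g = clamp(-HU/1000, 0, 1)`, so a -1000 HU voxel is pure gas and a 0 HU
#' voxel pure tissue. Gas volume is the sum of `g` times voxel volume,
#' tissue volume the complement; `pct_gas` is gas volume over region volume.
#'
#' @inheritParams mean_lung_attenuation
#' @return Named numeric: `gas_volume_mm3`, `tissue_volume_mm3`, `pct_gas`.
#' @export
gas_tissue_decomposition <- function(ct, mask, region = "whole") {
  stop_on_grid_mismatch(ct, mask, "gas_tissue_decomposition")
  sel <- region_mask(mask, region)
  check_region_nonempty(sel, region, "gas_tissue_decomposition")
  vv <- voxel_volume_mm3(ct)
  g <- pmin(pmax(-ct$values[sel] / 1000, 0), 1)
  gas <- sum(g) * vv
  tot <- sum(sel) * vv
  c(gas_volume_mm3 = gas, tissue_volume_mm3 = tot - gas,
    pct_gas = 100 * gas / tot)
}

#' Tidal volume
#'
#' Segmented-volume difference between end-inspiration and end-expiration,
#' `TV = V(P01) - V(P02)`, per region. Negative values are reported rather
#' than clamped, to surface segmentation or registration faults.
#'
#' @param mask_p01,mask_p02 [lung_labels()] for the two phases (grids may
#'   differ only in content, not geometry).
#' @param region `"whole"`, `"left"` or `"right"`.
#' @return Tidal volume in mm^3.
#' @export
tidal_volume <- function(mask_p01, mask_p02, region = "whole") {
  stop_on_grid_mismatch(mask_p01, mask_p02, "tidal_volume")
  lung_volume(mask_p01, region) - lung_volume(mask_p02, region)
}

#' Full aeration report for one phase
#'
#' Convenience wrapper computing every morphological biomarker for one
#' region of one phase.
#'
#' @inheritParams aeration_compartments
#' @param phase Phase tag copied into the report.
#' @return A one-row data.frame.
#' @export
aeration_report <- function(ct, mask, region = "whole",
                            boundaries_hu = c(-860, -435, -121, 121),
                            phase = ct$phase) {
  comp <- aeration_compartments(ct, mask, region, boundaries_hu)
  gt <- gas_tissue_decomposition(ct, mask, region)
  data.frame(region = region, phase = phase,
             volume_mm3 = lung_volume(mask, region),
             mla_hu = mean_lung_attenuation(ct, mask, region),
             pct_normo = comp[["pct_normo"]], pct_hypo = comp[["pct_hypo"]],
             pct_non = comp[["pct_non"]], pct_other = comp[["pct_other"]],
             gas_volume_mm3 = gt[["gas_volume_mm3"]],
             tissue_volume_mm3 = gt[["tissue_volume_mm3"]],
             pct_gas = gt[["pct_gas"]],
             stringsAsFactors = FALSE)
}
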