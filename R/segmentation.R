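# Classical left/right lung segmentation: air thresholding, border-connected
# background removal, largest-interior-component selection, morphological
# closing and hole filling. Stands in for the original deep-learning
# segmenter; externally produced masks are accepted through
# load_external_mask().

ball_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g <- g[g$x^2 + g$y^2 + g$z^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

binary_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  out <- .binary_dilate3(mask, dim(mask), ball_offsets(radius))
  array(out, dim(mask))
}

# erosion treating out-of-grid as foreground (so closing does not eat borders)
binary_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  !binary_dilate(!mask, radius)
}

binary_close <- function(mask, radius) binary_erode(binary_dilate(mask, radius), radius)

# components of `mask` touching any grid face
border_component_ids <- function(lab) {
  d <- dim(lab)
  ids <- c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])])
  setdiff(unique(ids), 0L)
}

fill_holes <- function(mask) {
  lab <- .label_components3(!mask, dim(mask))
  outside <- border_component_ids(lab)
  mask | !(lab == 0L | array(lab %in% outside, dim(mask)))
}

#' Segment the lungs from a CT volume
#'
#' Thresholds air at `threshold_hu` (default -200), removes the
#' border-connected exterior air, keeps the large interior air components,
#' applies morphological closing (ball radius `closing_radius_voxels`,
#' default 2) and 3D hole filling, and splits the result into left and
#' right lungs via [split_left_right()]. Dense focal lesions inside the
#' lung (above the air threshold) are recovered by the hole-filling step
#' when fully surrounded by parenchyma.
#'
#' @param ct A [ct_volume()].
#' @param params List with `threshold_hu` and `closing_radius_voxels`
#'   (see [analysis_config()]).
#' @return A [lung_labels()] (0 background, 1 left, 2 right).
#' @export
segment_lungs <- function(ct, params = list(threshold_hu = -200,
                                            closing_radius_voxels = 2)) {
  stopifnot(inherits(ct, "ct_volume"))
  thr <- params$threshold_hu %||% -200
  rad <- params$closing_radius_voxels %||% 2
  d <- dim(ct$values)
  air <- ct$values < thr
  lab <- .label_components3(air, d)
  outside <- border_component_ids(lab)
  interior <- lab != 0L & !array(lab %in% outside, d)
  if (!any(interior))
    stop("segment_lungs: empty segmentation (no interior air found); ",
         "check the HU threshold or the input volume", call. = FALSE)
  # keep components at least 1% the size of the largest interior one
  sizes <- tabulate(lab[interior])
  keep <- which(sizes >= 0.01 * max(sizes))
  lungs <- array(lab %in% keep, d) & interior
  lungs <- binary_close(lungs, rad)
  lungs <- fill_holes(lungs)
  # never leak into the border-connected exterior
  lungs <- lungs & !array(lab %in% outside, d)
  if (!any(lungs))
    stop("segment_lungs: segmentation collapsed to empty after morphology",
         call. = FALSE)
  split_left_right(lungs, spacing_mm = ct$spacing_mm, origin_mm = ct$origin_mm)
}

component_centroid_x <- function(lab, id) {
  idx <- which(lab == id)
  d <- dim(lab)
  mean((idx - 1L) %% d[1])
}

#' Split a binary lung mask into left and right lungs
#'
#' If the mask has two substantial connected components they are labelled by
#' centroid laterality (smaller x centroid = left = 1, larger = right = 2);
#' any small residual components join the side whose centroid is nearer in
#' x. If the lungs are fused into one component the mask is split by the
#' sagittal plane through the mask centroid.
#'
#' @param binary Logical 3D array (or 0/1 array) of lung voxels.
#' @param spacing_mm,origin_mm Grid descriptors for the returned labels.
#' @return A [lung_labels()].
#' @export
split_left_right <- function(binary, spacing_mm = 0.05, origin_mm = c(0, 0, 0)) {
  d <- dim(binary)
  binary <- array(as.logical(binary), d)
  if (!any(binary)) stop("split_left_right: empty mask", call. = FALSE)
  lab <- .label_components3(binary, d)
  sizes <- tabulate(lab[binary])
  ord <- order(sizes, decreasing = TRUE)
  out <- array(0L, d)
  if (length(sizes) >= 2L && sizes[ord[2]] >= 0.1 * sizes[ord[1]]) {
    c1 <- component_centroid_x(lab, ord[1])
    c2 <- component_centroid_x(lab, ord[2])
    left_id <- if (c1 < c2) ord[1] else ord[2]
    right_id <- if (c1 < c2) ord[2] else ord[1]
    out[lab == left_id] <- 1L
    out[lab == right_id] <- 2L
    extra <- setdiff(which(sizes > 0), c(left_id, right_id))
    if (length(extra)) {
      cl <- component_centroid_x(lab, left_id)
      cr <- component_centroid_x(lab, right_id)
      for (id in extra) {
        cx <- component_centroid_x(lab, id)
        out[lab == id] <- if (abs(cx - cl) <= abs(cx - cr)) 1L else 2L
      }
    }
  } else {
    # fused lungs: sagittal plane through the mask centroid
    idx <- which(binary)
    cx <- mean((idx - 1L) %% d[1])
    xcoord <- array(rep(0:(d[1] - 1L), times = prod(d[2:3])), d)
    out[binary & xcoord <= cx] <- 1L
    out[binary & xcoord > cx] <- 2L
  }
  lung_labels(out, spacing_mm = spacing_mm, origin_mm = origin_mm)
}

#' Load an externally produced lung mask
#'
#' Validates grid compatibility with the CT volume and relabels to the
#' package convention (0 background, 1 left, 2 right). Labels outside
#' \{0, 1, 2\} require an explicit `mapping`.
#'
#' @param path NIfTI label file.
#' @param ct The [ct_volume()] the mask belongs to.
#' @param mapping Optional named list/vector mapping foreign labels to
#'   0, 1 or 2, e.g. `c("10" = 1, "20" = 2)`.
#' @return A [lung_labels()].
#' @export
load_external_mask <- function(path, ct, mapping = NULL) {
  nii <- read_nifti_array(path)
  if (length(nii$dim) != 3L)
    stop("load_external_mask: expected a 3D label volume", call. = FALSE)
  lv <- round(nii$data)
  vals <- sort(unique(as.vector(lv)))
  if (!all(vals %in% 0:2)) {
    if (is.null(mapping))
      stop("load_external_mask: labels {", paste(vals, collapse = ", "),
           "} outside {0, 1, 2} and no mapping provided", call. = FALSE)
    out <- array(0L, dim(lv))
    for (from in names(mapping)) out[lv == as.numeric(from)] <- as.integer(mapping[[from]])
    lv <- out
  }
  mask <- lung_labels(lv, spacing_mm = nii$spacing, origin_mm = nii$origin)
  stop_on_grid_mismatch(ct, mask, "load_external_mask")
  mask
}

#' Dice overlap between two binary masks
#' @param a,b Logical arrays of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
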