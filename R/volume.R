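#' CT volume container
#'
#' A 3D scalar field of Hounsfield-unit values on a regular grid with
#' physical spacing, an origin, and a respiratory-phase tag. HU values are
#' stored as doubles even when the source file is integer, because all
#' downstream specific-gas-volume arithmetic is continuous.
#'
#' Coordinate convention: 0-based voxel indices; world coordinate =
#' origin + index * spacing; array axis order is (x, y, z) with the
#' cranio-caudal axis last.
#'
#' @param values 3D numeric array of HU values.
#' @param spacing_mm Voxel spacing in mm (length 1, recycled, or 3).
#' @param origin_mm World coordinate of voxel (0,0,0) in mm.
#' @param phase Respiratory phase, `"P01"` (end-inspiration),
#'   `"P02"` (end-expiration) or `NA`.
#' @param subject_id Optional subject identifier.
#' @param day Optional study day (integer).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(values, spacing_mm = 0.05, origin_mm = c(0, 0, 0),
                      phase = NA_character_, subject_id = NA_character_,
                      day = NA_integer_) {
  if (length(dim(values)) != 3L)
    stop("ct_volume: `values` must be a 3D array, got ",
         length(dim(values)), " dims", call. = FALSE)
  if (!all(is.finite(values)))
    stop("ct_volume: HU values must be finite", call. = FALSE)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0))
    stop("ct_volume: spacing_mm must be strictly positive", call. = FALSE)
  if (!is.na(phase) && !phase %in% c("P01", "P02"))
    stop("ct_volume: phase must be \"P01\", \"P02\" or NA", call. = FALSE)
  structure(list(values = array(as.double(values), dim(values)),
                 spacing_mm = spacing_mm,
                 origin_mm = rep_len(as.numeric(origin_mm), 3L),
                 phase = phase, subject_id = subject_id,
                 day = as.integer(day)),
            class = "ct_volume")
}

#' Lung label volume
#'
#' Integer voxel labels on the same grid as a [ct_volume()]:
#' 0 = background, 1 = left lung, 2 = right lung.
#'
#' @param labels 3D integer array with values in \{0, 1, 2\}.
#' @inheritParams ct_volume
#' @return An object of class `lung_labels`.
#' @export
lung_labels <- function(labels, spacing_mm = 0.05, origin_mm = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L)
    stop("lung_labels: `labels` must be a 3D array", call. = FALSE)
  lv <- as.integer(labels)
  if (anyNA(lv) || !all(lv %in% 0:2))
    stop("lung_labels: labels must be integers in {0, 1, 2}", call. = FALSE)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0))
    stop("lung_labels: spacing_mm must be strictly positive", call. = FALSE)
  structure(list(labels = array(lv, dim(labels)),
                 spacing_mm = spacing_mm,
                 origin_mm = rep_len(as.numeric(origin_mm), 3L)),
            class = "lung_labels")
}

#' Displacement field
#'
#' Per-voxel 3-vector displacement in mm, defined on the fixed (P01) grid and
#' mapping fixed-grid coordinates to the corresponding moving (P02)
#' coordinates (pull-back convention: `warped(x) = moving(x + u(x))`).
#'
#' @param vectors 4D numeric array `(nx, ny, nz, 3)`, displacement in mm.
#' @inheritParams ct_volume
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, spacing_mm = 0.05, origin_mm = c(0, 0, 0)) {
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement_field: `vectors` must be (nx, ny, nz, 3)", call. = FALSE)
  if (!all(is.finite(vectors)))
    stop("displacement_field: vectors must be finite", call. = FALSE)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0))
    stop("displacement_field: spacing_mm must be strictly positive", call. = FALSE)
  structure(list(vectors = array(as.double(vectors), d),
                 spacing_mm = spacing_mm,
                 origin_mm = rep_len(as.numeric(origin_mm), 3L)),
            class = "displacement_field")
}

grid_of <- function(x) {
  if (inherits(x, "ct_volume")) list(dim = dim(x$values), spacing = x$spacing_mm, origin = x$origin_mm)
  else if (inherits(x, "lung_labels")) list(dim = dim(x$labels), spacing = x$spacing_mm, origin = x$origin_mm)
  else if (inherits(x, "displacement_field")) list(dim = dim(x$vectors)[1:3], spacing = x$spacing_mm, origin = x$origin_mm)
  else stop("unsupported object of class ", paste(class(x), collapse = "/"), call. = FALSE)
}

#' Check that two volumes share a grid
#'
#' Grids are compatible when shapes are equal and spacings agree within
#' 1e-6 mm. Readers and pipeline stages reject incompatible grids rather
#' than silently resampling.
#'
#' @param a,b `ct_volume`, `lung_labels` or `displacement_field` objects.
#' @param tol_mm Spacing tolerance in mm.
#' @return A list with `ok` (logical) and `reason` (character, `""` on pass).
#' @export
validate_grid_compatibility <- function(a, b, tol_mm = 1e-6) {
  ga <- grid_of(a); gb <- grid_of(b)
  if (!identical(ga$dim, gb$dim))
    return(list(ok = FALSE, reason = sprintf(
      "shape mismatch: %s vs %s",
      paste(ga$dim, collapse = "x"), paste(gb$dim, collapse = "x"))))
  if (any(abs(ga$spacing - gb$spacing) > tol_mm))
    return(list(ok = FALSE, reason = sprintf(
      "spacing mismatch: (%s) vs (%s) mm",
      paste(format(ga$spacing), collapse = ", "),
      paste(format(gb$spacing), collapse = ", "))))
  list(ok = TRUE, reason = "")
}

stop_on_grid_mismatch <- function(a, b, where) {
  chk <- validate_grid_compatibility(a, b)
  if (!chk$ok) stop(where, ": ", chk$reason, call. = FALSE)
  invisible(TRUE)
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_volume %dx%dx%d, spacing %s mm, phase %s, HU [%0.1f, %0.1f]>\n",
              d[1], d[2], d[3], paste(format(x$spacing_mm), collapse = "x"),
              ifelse(is.na(x$phase), "?", x$phase),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.lung_labels <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<lung_labels %dx%dx%d: %d left, %d right voxels>\n",
              d[1], d[2], d[3], sum(x$labels == 1L), sum(x$labels == 2L)))
  invisible(x)
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$vectors)
  mag <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 + x$vectors[, , , 3]^2)
  cat(sprintf("<displacement_field %dx%dx%d, |u| max %0.3f mm>\n",
              d[1], d[2], d[3], max(mag)))
  invisible(x)
}

region_mask <- function(mask, region = c("whole", "left", "right")) {
  region <- match.arg(region)
  switch(region,
         whole = mask$labels > 0L,
         left  = mask$labels == 1L,
         right = mask$labels == 2L)
}
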