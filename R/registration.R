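# Deformable registration of the expiratory (P02) onto the inspiratory
# (P01) volume: Laplacian-of-Gaussian prefilter, classic multi-resolution
# Demons with Gaussian field regularisation, pull-back warping and Jacobian
# determinants. The LoG-filtered images drive the registration only; all
# densitometry downstream uses warped raw-HU images.

#' Registration parameters
#'
#' Declared defaults for the multi-resolution Demons registration; the
#' originating method publishes no level/iteration/smoothing values, so
#' these are pinned here and fully config-exposed.
#'
#' @param n_levels Number of pyramid levels (downsampling 4x/2x/1x for 3).
#' @param iterations_per_level Iterations from coarsest to finest.
#' @param update_smoothing_sigma_voxels Gaussian sigma applied to the
#'   accumulated field after each iteration.
#' @param laplacian_sigma_voxels Scale of the Laplacian-of-Gaussian
#'   prefilter.
#' @param convergence_tol Relative mean-squared intensity-difference change
#'   below which a level stops early.
#' @param max_displacement_voxels Sanity cap on the recovered field.
#' @return A list of class `registration_params`.
#' @export
registration_params <- function(n_levels = 3,
                                iterations_per_level = c(100, 50, 25),
                                update_smoothing_sigma_voxels = 1.5,
                                laplacian_sigma_voxels = 1.0,
                                convergence_tol = 1e-4,
                                max_displacement_voxels = 20) {
  stopifnot(n_levels >= 1,
            length(iterations_per_level) == n_levels,
            all(iterations_per_level > 0),
            update_smoothing_sigma_voxels > 0,
            laplacian_sigma_voxels > 0,
            convergence_tol > 0)
  structure(list(n_levels = as.integer(n_levels),
                 iterations_per_level = as.integer(iterations_per_level),
                 update_smoothing_sigma_voxels = update_smoothing_sigma_voxels,
                 laplacian_sigma_voxels = laplacian_sigma_voxels,
                 convergence_tol = convergence_tol,
                 max_displacement_voxels = max_displacement_voxels),
            class = c("registration_params", "list"))
}

smooth3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  array(.gauss_smooth3(arr, dim(arr), sigma), dim(arr))
}

shift3 <- function(a, axis, by) {
  # shift with edge replication; used for finite differences
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- pmin(pmax(idx[[axis]] + by, 1L), d[axis])
  idx[[axis]] <- src
  do.call(`[`, c(list(a), idx))
}

# central differences (one-sided replication at borders), per voxel step
diff_central <- function(a, axis) (shift3(a, axis, 1L) - shift3(a, axis, -1L)) / 2

#' Laplacian-of-Gaussian prefilter
#'
#' Gaussian smoothing at scale `sigma` followed by the 6-neighbour discrete
#' Laplacian. The response is zero on constant images and invariant to
#' adding a constant offset, which makes the subsequent registration
#' sensitive to structure rather than to overall intensity (which varies
#' with lung volume between phases). Sign convention: a single bright voxel
#' yields a centre-negative response.
#'
#' @param ct A [ct_volume()].
#' @param sigma Gaussian scale in voxels (> 0).
#' @return A [ct_volume()] holding the filter response (not HU; never used
#'   for densitometry).
#' @export
laplacian_prefilter <- function(ct, sigma = 1.0) {
  stopifnot(inherits(ct, "ct_volume"), sigma > 0)
  s <- smooth3(ct$values, sigma)
  lap <- shift3(s, 1L, 1L) + shift3(s, 1L, -1L) +
         shift3(s, 2L, 1L) + shift3(s, 2L, -1L) +
         shift3(s, 3L, 1L) + shift3(s, 3L, -1L) - 6 * s
  out <- ct
  out$values <- lap
  out
}

pyramid_dims <- function(d, factor) pmax(8L, as.integer(ceiling(d / factor)))

resample_arr <- function(a, dim_out, nearest = FALSE) {
  array(.resample3(a, dim(a), as.integer(dim_out), nearest), dim_out)
}

#' Multi-resolution Demons registration
#'
#' Classic Demons: per-iteration update
#' `u += (m - f) * grad(f) / (|grad(f)|^2 + (m - f)^2)` on the (filtered)
#' fixed/moving pair, with Gaussian smoothing of the accumulated field after
#' every iteration, run coarse-to-fine with field upsampling between levels.
#' Inputs should be [laplacian_prefilter()] responses of the P01 (fixed) and
#' P02 (moving) volumes.
#'
#' @param fixed_filtered,moving_filtered Grid-compatible [ct_volume()]s.
#' @param params A [registration_params()].
#' @param verbose Print per-level residuals.
#' @return A [displacement_field()] in mm on the fixed grid (pull-back
#'   convention).
#' @export
demons_multiresolution <- function(fixed_filtered, moving_filtered,
                                   params = registration_params(),
                                   verbose = FALSE) {
  stop_on_grid_mismatch(fixed_filtered, moving_filtered, "demons_multiresolution")
  f0 <- fixed_filtered$values
  m0 <- moving_filtered$values
  d0 <- dim(f0)
  nl <- params$n_levels
  u <- NULL  # list of 3 arrays, voxel units of current level

  for (lev in seq_len(nl)) {
    factor <- 2^(nl - lev)
    dl <- if (factor > 1) pyramid_dims(d0, factor) else d0
    aa <- factor / 2  # anti-alias scale
    f <- if (factor > 1) resample_arr(smooth3(f0, aa), dl) else f0
    m <- if (factor > 1) resample_arr(smooth3(m0, aa), dl) else m0

    if (is.null(u)) {
      u <- list(array(0, dl), array(0, dl), array(0, dl))
    } else {
      old <- dim(u[[1]])
      scale <- (dl - 1) / pmax(old - 1, 1L)
      u <- lapply(1:3, function(k) resample_arr(u[[k]], dl) * scale[k])
    }

    g <- list(diff_central(f, 1L), diff_central(f, 2L), diff_central(f, 3L))
    gm2 <- g[[1]]^2 + g[[2]]^2 + g[[3]]^2

    mse_prev <- Inf
    best_mse <- Inf
    best_u <- u
    stall <- 0L
    grow <- 0L
    du_prev <- Inf
    for (it in seq_len(params$iterations_per_level[lev])) {
      mw <- array(.warp_pullback3(m, dl, u[[1]], u[[2]], u[[3]], 0, FALSE), dl)
      diffv <- mw - f
      mse <- mean(diffv^2)
      if (mse < best_mse) {
        best_mse <- mse
        best_u <- u
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      # stop on stagnation (no improvement for 10 iterations) or convergence
      if (stall >= 10L) break
      if (is.finite(mse_prev) &&
          abs(mse_prev - mse) / max(mse_prev, .Machine$double.eps) <
            params$convergence_tol) break
      mse_prev <- mse
      denom <- gm2 + diffv^2
      w <- diffv / denom
      w[denom < 1e-12] <- 0
      for (k in 1:3) {
        u[[k]] <- smooth3(u[[k]] - w * g[[k]],
                          params$update_smoothing_sigma_voxels)
      }
      du_mean <- mean(abs(w) * sqrt(gm2))
      if (du_mean > du_prev && mse > 1.5 * best_mse) grow <- grow + 1L
      else grow <- 0L
      if (grow >= 10L)
        stop("demons_multiresolution: diverging (mean update magnitude ",
             "growing for 10 consecutive iterations)", call. = FALSE)
      du_prev <- du_mean
    }
    u <- best_u
    mse_prev <- best_mse
    if (verbose)
      message(sprintf("level %d (%s): MSE %.4g after %d iters", lev,
                      paste(dl, collapse = "x"), mse_prev, it))
  }

  mag <- sqrt(u[[1]]^2 + u[[2]]^2 + u[[3]]^2)
  if (max(mag) > params$max_displacement_voxels)
    stop("demons_multiresolution: displacement exceeds sanity cap of ",
         params$max_displacement_voxels, " voxels", call. = FALSE)
  sp <- fixed_filtered$spacing_mm
  vec <- array(0, c(d0, 3L))
  for (k in 1:3) vec[, , , k] <- u[[k]] * sp[k]
  displacement_field(vec, spacing_mm = sp, origin_mm = fixed_filtered$origin_mm)
}

#' Warp a volume or label mask through a displacement field
#'
#' Pull-back warping on the fixed grid: `warped(x) = moving(x + u(x))`.
#' HU volumes are interpolated trilinearly with out-of-field samples set to
#' -1000 HU (air); label volumes use nearest-neighbour with background fill,
#' so the label set is preserved.
#'
#' @param moving A [ct_volume()] or [lung_labels()].
#' @param field A [displacement_field()] on the same grid.
#' @param fill Out-of-field fill value for scalar volumes (default -1000
#'   HU; use 0 when warping filter responses).
#' @return The warped object, same class as `moving`.
#' @export
warp_volume <- function(moving, field, fill = -1000) {
  stopifnot(inherits(field, "displacement_field"))
  stop_on_grid_mismatch(moving, field, "warp_volume")
  sp <- field$spacing_mm
  d <- grid_of(field)$dim
  ux <- field$vectors[, , , 1] / sp[1]
  uy <- field$vectors[, , , 2] / sp[2]
  uz <- field$vectors[, , , 3] / sp[3]
  if (inherits(moving, "ct_volume")) {
    w <- array(.warp_pullback3(moving$values, d, ux, uy, uz, fill, FALSE), d)
    out <- moving
    out$values <- w
    out
  } else {
    w <- array(as.integer(.warp_pullback3(as.double(moving$labels), d,
                                          ux, uy, uz, 0, TRUE)), d)
    lung_labels(w, spacing_mm = moving$spacing_mm, origin_mm = moving$origin_mm)
  }
}

#' Jacobian determinant of a displacement field
#'
#' Determinant of `I + grad(u)` by central differences in physical units.
#' Values below 1 indicate local compression.
#'
#' @param field A [displacement_field()].
#' @return A 3D array of per-voxel determinants.
#' @export
jacobian_determinant <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  sp <- field$spacing_mm
  J11 <- 1 + diff_central(field$vectors[, , , 1], 1L) / sp[1]
  J12 <-     diff_central(field$vectors[, , , 1], 2L) / sp[2]
  J13 <-     diff_central(field$vectors[, , , 1], 3L) / sp[3]
  J21 <-     diff_central(field$vectors[, , , 2], 1L) / sp[1]
  J22 <- 1 + diff_central(field$vectors[, , , 2], 2L) / sp[2]
  J23 <-     diff_central(field$vectors[, , , 2], 3L) / sp[3]
  J31 <-     diff_central(field$vectors[, , , 3], 1L) / sp[1]
  J32 <-     diff_central(field$vectors[, , , 3], 2L) / sp[2]
  J33 <- 1 + diff_central(field$vectors[, , , 3], 3L) / sp[3]
  J11 * (J22 * J33 - J23 * J32) -
    J12 * (J21 * J33 - J23 * J31) +
    J13 * (J21 * J32 - J22 * J31)
}

#' Register an expiratory to an inspiratory volume
#'
#' Convenience wrapper: LoG-prefilters both raw-HU volumes, runs
#' [demons_multiresolution()], and returns the field plus the warped raw
#' P02 volume (densitometry must never use filtered intensities).
#'
#' @param p01,p02 Raw-HU [ct_volume()]s (fixed and moving).
#' @param params A [registration_params()].
#' @param verbose Passed through.
#' @return List with `field` ([displacement_field()]) and `warped_p02`.
#' @export
register_pair <- function(p01, p02, params = registration_params(),
                          verbose = FALSE) {
  stop_on_grid_mismatch(p01, p02, "register_pair")
  ff <- laplacian_prefilter(p01, params$laplacian_sigma_voxels)
  mf <- laplacian_prefilter(p02, params$laplacian_sigma_voxels)
  field <- demons_multiresolution(ff, mf, params, verbose = verbose)
  list(field = field, warped_p02 = warp_volume(p02, field))
}
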