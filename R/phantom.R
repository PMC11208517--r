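# Synthetic thorax phantom: paired inspiratory/expiratory micro-CT volumes
# of a mouse-like thorax with ground-truth lung masks, lesion labels, an
# analytic mass-conserving respiratory deformation and longitudinal cohort
# structure. Every downstream stage of the pipeline is testable against the
# truth objects produced here.

#' Phantom specification
#'
#' Geometry and intensity model of the synthetic thorax: a soft-tissue body
#' ellipsoid containing two disjoint lung ellipsoids, surrounded by air.
#' Defaults emulate the acquisition the pipeline targets: 50 um isotropic
#' voxels, aerated parenchyma around -550 HU with 45 HU texture, soft
#' tissue at 40 HU, additive Gaussian reconstruction noise of 25 HU.
#'
#' @param grid_shape Voxels per axis (3 ints, each >= 32).
#' @param voxel_spacing_mm Isotropic spacing (default 0.05 mm).
#' @param body_hu Soft-tissue HU (default 40).
#' @param parenchyma_hu_mean,parenchyma_hu_sd Aerated-lung HU distribution
#'   (defaults -550, 45).
#' @param noise_sd_hu Additive Gaussian noise SD applied to both phases
#'   after the intensity transform (default 25).
#' @param rng_seed Integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), voxel_spacing_mm = 0.05,
                         body_hu = 40, parenchyma_hu_mean = -550,
                         parenchyma_hu_sd = 45, noise_sd_hu = 25,
                         rng_seed = 1L) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  if (any(grid_shape <= 0)) stop("phantom_spec: grid_shape must be positive", call. = FALSE)
  if (voxel_spacing_mm <= 0) stop("phantom_spec: voxel_spacing_mm must be > 0", call. = FALSE)
  hu <- c(body_hu, parenchyma_hu_mean)
  if (any(hu < -1000 | hu > 1000))
    stop("phantom_spec: HU parameters must lie in [-1000, 1000]", call. = FALSE)
  if (parenchyma_hu_sd < 0 || noise_sd_hu < 0)
    stop("phantom_spec: SDs must be non-negative", call. = FALSE)
  structure(list(grid_shape = grid_shape, voxel_spacing_mm = voxel_spacing_mm,
                 body_hu = body_hu, parenchyma_hu_mean = parenchyma_hu_mean,
                 parenchyma_hu_sd = parenchyma_hu_sd, noise_sd_hu = noise_sd_hu,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Lesion specification
#'
#' Focal fibrotic blobs of near-tissue density. Lesion HU must stay above
#' -121 HU so planted voxels fall in the non-aerated aeration range.
#' `placement_bias` reproduces the apical, left-lobe-dominant lesion
#' topography of bleomycin fibrosis models.
#'
#' @param count Number of blobs (>= 0).
#' @param radius_mm_range `(min, max)` blob radius in mm.
#' @param hu_mean,hu_sd Lesion HU distribution (defaults 20, 40).
#' @param placement_bias `"apical_left"`, `"apical"` or `"uniform"`.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(count = 4, radius_mm_range = c(0.2, 0.35),
                        hu_mean = 20, hu_sd = 40,
                        placement_bias = c("apical_left", "apical", "uniform")) {
  if (count < 0) stop("lesion_spec: count must be >= 0", call. = FALSE)
  if (any(radius_mm_range <= 0) || radius_mm_range[1] > radius_mm_range[2])
    stop("lesion_spec: radii must be positive and ordered", call. = FALSE)
  if (hu_mean <= -121)
    stop("lesion_spec: hu_mean must be > -121 HU (non-aerated range)", call. = FALSE)
  structure(list(count = as.integer(count), radius_mm_range = radius_mm_range,
                 hu_mean = hu_mean, hu_sd = hu_sd,
                 placement_bias = match.arg(placement_bias)),
            class = "lesion_spec")
}

#' Respiratory deformation model
#'
#' Analytic caudo-cranial compression: the displacement is purely axial,
#' `u_z(x, y, z) = -amplitude * w(x, y) * S(z) * (1 - stiffness * L(x,y,z))`
#' with a Gaussian in-plane window `w` (scale `smoothness_mm`), a smoothstep
#' axial profile `S` rising from the lung base to the apex, and a smoothed
#' lesion indicator `L` that makes fibrotic tissue deform near-rigidly so
#' its Delta-SVg stays near zero. The analytic form keeps the exact
#' Jacobian computable, which enables mass-conservation oracles.
#'
#' @param amplitude_mm Peak apex displacement (default 0.15 mm = 3 voxels
#'   at 50 um).
#' @param smoothness_mm Gaussian scale of the in-plane window.
#' @param lesion_stiffness In `[0, 1]`; 1 = rigid lesions (default 0.9).
#' @return An object of class `deformation_model`.
#' @export
deformation_model <- function(amplitude_mm = 0.15, smoothness_mm = 1.0,
                              lesion_stiffness = 0.9) {
  if (amplitude_mm < 0) stop("deformation_model: amplitude_mm must be >= 0", call. = FALSE)
  if (smoothness_mm <= 0) stop("deformation_model: smoothness_mm must be > 0", call. = FALSE)
  if (lesion_stiffness < 0 || lesion_stiffness > 1)
    stop("deformation_model: lesion_stiffness must be in [0, 1]", call. = FALSE)
  structure(list(amplitude_mm = amplitude_mm, smoothness_mm = smoothness_mm,
                 lesion_stiffness = lesion_stiffness),
            class = "deformation_model")
}

phantom_coords <- function(d) {
  list(x = array(rep(0:(d[1] - 1L), times = prod(d[2:3])), d),
       y = array(rep(rep(0:(d[2] - 1L), each = d[1]), times = d[3]), d),
       z = array(rep(0:(d[3] - 1L), each = prod(d[1:2])), d))
}

inside_ellipsoid <- function(co, center, semi) {
  ((co$x - center[1]) / semi[1])^2 + ((co$y - center[2]) / semi[2])^2 +
    ((co$z - center[3]) / semi[3])^2 <= 1
}

#' Generate the baseline (end-inspiratory) anatomy
#'
#' Two disjoint ellipsoidal lungs inside a soft-tissue body ellipsoid;
#' voxels outside the body are air at -1000 HU; lung voxels are drawn from
#' the parenchyma HU distribution. The returned mask labels the left
#' (lower x, label 1) and right (label 2) lungs separately.
#'
#' @param spec A [phantom_spec()]. Grids below 32 voxels on any axis cannot
#'   contain two lungs and are rejected.
#' @return List with `ct` ([ct_volume()], phase P01) and `mask`
#'   ([lung_labels()]).
#' @export
generate_anatomy <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  if (any(d < 32L))
    stop("generate_anatomy: grid too small to contain two lungs ",
         "(need >= 32 voxels per axis)", call. = FALSE)
  set.seed(spec$rng_seed)
  co <- phantom_coords(d)
  ctr <- (d - 1) / 2
  body <- inside_ellipsoid(co, ctr, c(0.42, 0.38, 0.46) * d)
  lung_semi <- c(0.14, 0.24, 0.32) * d
  left  <- inside_ellipsoid(co, ctr + c(-0.19 * d[1], 0, 0), lung_semi)
  right <- inside_ellipsoid(co, ctr + c(+0.19 * d[1], 0, 0), lung_semi)
  vals <- array(-1000, d)
  vals[body] <- spec$body_hu
  lungs <- left | right
  nlung <- sum(lungs)
  vals[lungs] <- rnorm(nlung, spec$parenchyma_hu_mean, spec$parenchyma_hu_sd)
  vals <- pmin(pmax(vals, -1000), 1000)
  lab <- array(0L, d)
  lab[left] <- 1L
  lab[right] <- 2L
  list(ct = ct_volume(vals, spacing_mm = spec$voxel_spacing_mm, phase = "P01"),
       mask = lung_labels(lab, spacing_mm = spec$voxel_spacing_mm))
}

#' Plant fibrotic lesions
#'
#' Overwrites spherical regions of lung parenchyma with draws from the
#' lesion HU distribution. Placement respects the spatial bias of the
#' lesion spec (apical = high z, left = label 1). Lesions are clipped to
#' the lung mask.
#'
#' @param ct A [ct_volume()] from [generate_anatomy()].
#' @param mask The matching [lung_labels()].
#' @param lesions A [lesion_spec()].
#' @param seed Optional seed for placement and intensities.
#' @param centers,radii_mm Optional fixed lesion centers (matrix, voxel
#'   indices) and radii; used by the cohort simulator to grow the same
#'   lesions over time.
#' @return List with `ct` (lesioned copy) and `lesion_labels` (logical 3D
#'   array, subset of the lung mask).
#' @export
plant_lesions <- function(ct, mask, lesions, seed = NULL,
                          centers = NULL, radii_mm = NULL) {
  stopifnot(inherits(lesions, "lesion_spec"))
  stop_on_grid_mismatch(ct, mask, "plant_lesions")
  d <- dim(ct$values)
  lesion_lab <- array(FALSE, d)
  if (lesions$count == 0L && is.null(centers))
    return(list(ct = ct, lesion_labels = lesion_lab))
  if (!is.null(seed)) set.seed(seed)
  sp <- ct$spacing_mm
  inlung <- mask$labels > 0L
  if (is.null(centers)) {
    co <- phantom_coords(d)
    w <- array(1, d)
    if (lesions$placement_bias %in% c("apical", "apical_left"))
      w <- w * (1 + 2 * (co$z > 2 / 3 * (d[3] - 1)))
    if (lesions$placement_bias == "apical_left")
      w <- w * (1 + 2 * (mask$labels == 1L))
    cand <- which(inlung)
    centers_idx <- sample(cand, lesions$count, prob = w[cand])
    centers <- cbind((centers_idx - 1L) %% d[1],
                     ((centers_idx - 1L) %/% d[1]) %% d[2],
                     (centers_idx - 1L) %/% (d[1] * d[2]))
    radii_mm <- runif(lesions$count, lesions$radius_mm_range[1],
                      lesions$radius_mm_range[2])
  }
  lung_extent_mm <- apply(which(inlung, arr.ind = TRUE), 2, function(v) diff(range(v))) * sp
  if (any(radii_mm > max(lung_extent_mm)))
    stop("plant_lesions: lesion radius exceeds the lung extent", call. = FALSE)
  co <- phantom_coords(d)
  for (i in seq_len(nrow(centers))) {
    if (radii_mm[i] <= 0) next
    r2 <- ((co$x - centers[i, 1]) * sp[1])^2 +
          ((co$y - centers[i, 2]) * sp[2])^2 +
          ((co$z - centers[i, 3]) * sp[3])^2
    lesion_lab <- lesion_lab | (r2 <= radii_mm[i]^2 & inlung)
  }
  frac <- sum(lesion_lab) / sum(inlung)
  if (frac > 0.8)
    stop(sprintf("plant_lesions: requested lesions cover %.0f%% of the lung ",
                 100 * frac), "(> 80%); infeasible spec", call. = FALSE)
  out <- ct
  n <- sum(lesion_lab)
  if (n > 0)
    out$values[lesion_lab] <- pmin(pmax(
      rnorm(n, lesions$hu_mean, lesions$hu_sd), -1000), 1000)
  list(ct = out, lesion_labels = lesion_lab,
       centers = centers, radii_mm = radii_mm)
}

# mass-conserving intensity rule: density scales with inverse local volume
# change; pure gas (-1000 HU) carries no mass and is invariant under any J
hu_mass_transform <- function(hu, J) pmin((hu + 1000) / J - 1000, 1000)

build_axial_displacement <- function(d, sp, model, lesion_labels = NULL) {
  co <- phantom_coords(d)
  ctr_mm <- (d - 1) / 2 * sp
  w <- exp(-(((co$x * sp[1] - ctr_mm[1])^2 + (co$y * sp[2] - ctr_mm[2])^2) /
               (2 * model$smoothness_mm^2)))
  zmm <- co$z * sp[3]
  Zl <- 0.15 * (d[3] - 1) * sp[3]
  Zh <- 0.85 * (d[3] - 1) * sp[3]
  t <- pmin(pmax((zmm - Zl) / (Zh - Zl), 0), 1)
  S <- t * t * (3 - 2 * t)
  uz <- -model$amplitude_mm * w * S
  if (!is.null(lesion_labels) && any(lesion_labels) && model$lesion_stiffness > 0) {
    # stiffness must hold over the whole lesion including its rim (fibrotic
    # tissue tethers its immediate neighbourhood), so the indicator is
    # dilated before smoothing; plain smoothing would leave a compliant
    # shell inside the lesion boundary
    L <- smooth3(array(as.double(binary_dilate(lesion_labels, 2)), d), 1.5)
    uz <- uz * (1 - model$lesion_stiffness * pmin(L, 1))
  }
  uz
}

#' Apply the analytic respiratory deformation
#'
#' Produces the end-expiratory volume from the end-inspiratory one: the
#' analytic axial compression field is applied and voxel intensities follow
#' the mass-conserving rule `HU_exp = (HU_insp + 1000) / J - 1000` (clipped
#' at 1000 HU), where `J` is the local Jacobian determinant of the motion
#' (J < 1 = compression, so parenchyma densifies at expiration while pure
#' gas at -1000 HU is invariant). Because the field is purely axial and
#' monotone per column, it is inverted exactly per (x, y) column, giving an
#' expiratory image, the true fixed-grid (P01 -> P02) displacement field,
#' the true Jacobian map and the true expiratory mask.
#'
#' @param ct_insp Inspiratory [ct_volume()].
#' @param mask Its [lung_labels()].
#' @param model A [deformation_model()].
#' @param lesion_labels Optional logical array of lesion voxels (stiffened).
#' @param noise_sd_hu Additive Gaussian noise applied to the expiratory
#'   volume after the intensity transform (default 0).
#' @return List: `ct_exp` ([ct_volume()], phase P02), `field`
#'   ([displacement_field()] on the P01 grid), `jacobian` (3D array),
#'   `mask_exp` ([lung_labels()]).
#' @export
apply_respiratory_deformation <- function(ct_insp, mask, model,
                                          lesion_labels = NULL,
                                          noise_sd_hu = 0) {
  stopifnot(inherits(model, "deformation_model"))
  stop_on_grid_mismatch(ct_insp, mask, "apply_respiratory_deformation")
  d <- dim(ct_insp$values)
  sp <- ct_insp$spacing_mm
  uz_mm <- build_axial_displacement(d, sp, model, lesion_labels)
  J <- 1 + diff_central(uz_mm, 3L) / sp[3]
  if (any(J <= 0))
    stop("apply_respiratory_deformation: non-invertible field (J <= 0); ",
         "reduce amplitude_mm", call. = FALSE)

  exp_vals <- ct_insp$values
  exp_lab <- mask$labels
  if (model$amplitude_mm > 0) {
    uz_vox <- uz_mm / sp[3]
    zg <- 0:(d[3] - 1L)
    exp_vals <- array(0, d)
    exp_lab <- array(0L, d)
    for (ix in seq_len(d[1])) {
      for (iy in seq_len(d[2])) {
        f <- zg + uz_vox[ix, iy, ]       # insp index -> exp coordinate
        zstar <- approx(f, zg, xout = zg, rule = 2)$y  # exp index -> insp coord
        hu <- approx(zg, ct_insp$values[ix, iy, ], xout = zstar, rule = 2)$y
        Js <- approx(zg, J[ix, iy, ], xout = zstar, rule = 2)$y
        exp_vals[ix, iy, ] <- hu_mass_transform(hu, Js)
        zi <- pmin(pmax(round(zstar), 0), d[3] - 1L)
        exp_lab[ix, iy, ] <- mask$labels[ix, iy, zi + 1L]
      }
    }
  }
  if (noise_sd_hu > 0)
    exp_vals <- exp_vals + rnorm(length(exp_vals), 0, noise_sd_hu)
  vec <- array(0, c(d, 3L))
  vec[, , , 3] <- uz_mm
  list(ct_exp = ct_volume(pmin(pmax(exp_vals, -1000), 1000), spacing_mm = sp,
                          origin_mm = ct_insp$origin_mm, phase = "P02",
                          subject_id = ct_insp$subject_id, day = ct_insp$day),
       field = displacement_field(vec, spacing_mm = sp,
                                  origin_mm = ct_insp$origin_mm),
       jacobian = J,
       mask_exp = lung_labels(exp_lab, spacing_mm = sp,
                              origin_mm = mask$origin_mm))
}

#' Generate a complete phantom scan pair with ground truth
#'
#' Convenience wrapper: anatomy, optional lesions, analytic deformation,
#' additive noise on both phases, plus the truth bundle (masks for both
#' phases, lesion labels, true displacement field, true Jacobian and exact
#' per-region aeration-class voxel fractions computed on the noiseless
#' volume).
#'
#' @param spec A [phantom_spec()].
#' @param lesions Optional [lesion_spec()] (`NULL` = lesion-free).
#' @param model A [deformation_model()].
#' @param subject_id,day Provenance tags.
#' @return List with `p01`, `p02`, `mask_p01`, `mask_p02`, `lesion_labels`,
#'   `field`, `jacobian`, `truth` (list incl. `compartment_fractions`).
#' @export
phantom_pair <- function(spec = phantom_spec(), lesions = NULL,
                         model = deformation_model(),
                         subject_id = NA_character_, day = NA_integer_) {
  anat <- generate_anatomy(spec)
  lesion_labels <- array(FALSE, spec$grid_shape)
  ct <- anat$ct
  if (!is.null(lesions) && lesions$count > 0L) {
    pl <- plant_lesions(ct, anat$mask, lesions, seed = spec$rng_seed + 1L)
    ct <- pl$ct
    lesion_labels <- pl$lesion_labels
  }
  truth_fracs <- lapply(setNames(nm = c("whole", "left", "right")), function(r) {
    sel <- region_mask(anat$mask, r)
    hu <- ct$values[sel]
    n <- length(hu)
    c(normo = sum(hu >= -860 & hu <= -435) / n,
      hypo = sum(hu > -435 & hu < -121) / n,
      non = sum(hu >= -121 & hu <= 121) / n,
      other = sum(hu < -860 | hu > 121) / n)
  })
  set.seed(spec$rng_seed + 2L)
  def <- apply_respiratory_deformation(ct, anat$mask, model, lesion_labels,
                                       noise_sd_hu = spec$noise_sd_hu)
  p01 <- ct
  if (spec$noise_sd_hu > 0) {
    p01$values <- pmin(pmax(
      p01$values + rnorm(length(p01$values), 0, spec$noise_sd_hu), -1000), 1000)
  }
  p01$subject_id <- subject_id; p01$day <- as.integer(day)
  p02 <- def$ct_exp
  p02$subject_id <- subject_id; p02$day <- as.integer(day)
  list(p01 = p01, p02 = p02, mask_p01 = anat$mask, mask_p02 = def$mask_exp,
       lesion_labels = lesion_labels, field = def$field,
       jacobian = def$jacobian,
       truth = list(compartment_fractions = truth_fracs,
                    lesion_fraction = sum(lesion_labels) / sum(anat$mask$labels > 0)))
}

#' Cohort simulation plan
#'
#' Longitudinal structure mirroring a bleomycin time-course with delayed
#' antifibrotic treatment: day 0 is lesion-free for every group (the basal
#' calibration set); the BLM group's lesion burden grows linearly with day;
#' treated groups grow at `treated_growth_factor` of the BLM rate after
#' their treatment start day; the SAL group stays lesion-free throughout.
#'
#' @param n_subjects Subjects per group.
#' @param groups Subset of `c("SAL", "BLM", "NINT_7_28", "NINT_14_28")`.
#' @param timepoints_days Scan days (must include 0).
#' @param treatment_start_day Named list of start days for treated groups;
#'   each must be one of the timepoints.
#' @param max_severity Lesion-burden scale reached by the untreated group
#'   at the final day (radius growth is severity^(1/3) so lesion volume
#'   tracks severity).
#' @param treated_growth_factor Residual growth rate under treatment.
#' @param rng_seed Integer seed.
#' @return An object of class `cohort_plan`.
#' @export
cohort_plan <- function(n_subjects = 3,
                        groups = c("SAL", "BLM", "NINT_7_28", "NINT_14_28"),
                        timepoints_days = c(0, 7, 14, 21, 28),
                        treatment_start_day = list(NINT_7_28 = 7, NINT_14_28 = 14),
                        max_severity = 1.0,
                        treated_growth_factor = 0.25,
                        rng_seed = 1L) {
  groups <- match.arg(groups, several.ok = TRUE)
  if (!0 %in% timepoints_days)
    stop("cohort_plan: day 0 (basal, lesion-free) must be a timepoint", call. = FALSE)
  for (g in intersect(groups, names(treatment_start_day)))
    if (!treatment_start_day[[g]] %in% timepoints_days)
      stop("cohort_plan: treatment_start_day for ", g,
           " must be one of the timepoints", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), groups = groups,
                 timepoints_days = sort(timepoints_days),
                 treatment_start_day = treatment_start_day,
                 max_severity = max_severity,
                 treated_growth_factor = treated_growth_factor,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_plan")
}

# severity in [0, max]: linear growth, attenuated after treatment start
lesion_severity <- function(plan, group, day) {
  if (group == "SAL") return(0)
  final <- max(plan$timepoints_days)
  start <- plan$treatment_start_day[[group]]
  if (is.null(start)) {
    sev <- day / final
  } else {
    f <- plan$treated_growth_factor
    sev <- (pmin(day, start) + f * pmax(day - start, 0)) / final
  }
  plan$max_severity * sev
}

#' Simulate a longitudinal phantom cohort to disk
#'
#' Writes one inspiratory/expiratory scan pair per subject per timepoint,
#' plus truth files (both-phase masks, lesion labels, displacement field,
#' Jacobian), all as NIfTI, and a manifest CSV. Lesions for a subject keep
#' fixed centers across days and grow with the group's severity schedule,
#' so each subject's true lesion fraction is non-decreasing in time and
#' treated subjects' growth attenuates after their treatment start.
#'
#' @param plan A [cohort_plan()].
#' @param spec A [phantom_spec()] (per-subject seeds are derived from
#'   `plan$rng_seed`).
#' @param out_dir Output directory (created if missing).
#' @param lesions A [lesion_spec()] giving the day-final lesion geometry.
#' @param model A [deformation_model()].
#' @return The manifest as a data.frame (also written to
#'   `out_dir/manifest.csv`) with columns subject_id, group, day,
#'   p01_path, p02_path, mask_path, mask_p02_path, truth_prefix.
#' @export
simulate_cohort <- function(plan, spec = phantom_spec(), out_dir,
                            lesions = lesion_spec(), model = deformation_model()) {
  stopifnot(inherits(plan, "cohort_plan"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop("simulate_cohort: cannot create output directory ", out_dir, call. = FALSE)
  rows <- list()
  subj_idx <- 0L
  for (g in plan$groups) {
    for (s in seq_len(plan$n_subjects)) {
      subj_idx <- subj_idx + 1L
      sid <- sprintf("%s_%02d", g, s)
      sseed <- (plan$rng_seed * 131L + subj_idx * 7L) %% 2147483L
      sspec <- spec
      sspec$rng_seed <- sseed
      anat <- generate_anatomy(sspec)

      # fixed lesion geometry for this subject, grown over time
      set.seed(sseed + 1L)
      geom <- NULL
      if (g != "SAL" && lesions$count > 0L) {
        geom <- plant_lesions(anat$ct, anat$mask, lesions, seed = sseed + 1L)
      }
      for (day in plan$timepoints_days) {
        sev <- lesion_severity(plan, g, day)
        ct <- anat$ct
        lesion_labels <- array(FALSE, sspec$grid_shape)
        if (!is.null(geom) && sev > 0) {
          pl <- plant_lesions(anat$ct, anat$mask, lesions, seed = sseed + 2L + day,
                              centers = geom$centers,
                              radii_mm = geom$radii_mm * sev^(1 / 3))
          ct <- pl$ct
          lesion_labels <- pl$lesion_labels
        }
        set.seed(sseed + 100L + day)
        def <- apply_respiratory_deformation(ct, anat$mask, model, lesion_labels,
                                             noise_sd_hu = sspec$noise_sd_hu)
        p01 <- ct
        if (sspec$noise_sd_hu > 0)
          p01$values <- pmin(pmax(p01$values +
            rnorm(length(p01$values), 0, sspec$noise_sd_hu), -1000), 1000)
        p01$phase <- "P01"; p01$subject_id <- sid; p01$day <- as.integer(day)

        prefix <- file.path(out_dir, sprintf("%s_d%02d", sid, day))
        paths <- list(p01 = paste0(prefix, "_P01.nii.gz"),
                      p02 = paste0(prefix, "_P02.nii.gz"),
                      mask = paste0(prefix, "_mask_P01.nii.gz"),
                      mask_p02 = paste0(prefix, "_mask_P02.nii.gz"),
                      lesions = paste0(prefix, "_lesions.nii.gz"),
                      field = paste0(prefix, "_field.nii.gz"))
        write_volume(p01, paths$p01)
        write_volume(def$ct_exp, paths$p02)
        write_labels(anat$mask, paths$mask)
        write_labels(def$mask_exp, paths$mask_p02)
        write_nifti_array(array(as.integer(lesion_labels), sspec$grid_shape),
                          paths$lesions, sspec$voxel_spacing_mm,
                          datatype = "int16")
        write_field(def$field, paths$field)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, group = g, day = day,
          p01_path = paths$p01, p02_path = paths$p02,
          mask_path = paths$mask, mask_p02_path = paths$mask_p02,
          truth_prefix = prefix, stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
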