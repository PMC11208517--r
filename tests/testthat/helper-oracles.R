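# Shared fixtures (cached per test run; phantom generation is the costly
# part) and independent brute-force oracles. Oracles are deliberately
# naive voxel loops, sharing no code with the implementation they check.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx, inherits = FALSE))
    assign(name, force(expr), envir = .fx)
  get(name, envir = .fx, inherits = FALSE)
}

# 48^3 noisy lesion-free pair, default deformation
pair48 <- function() fixture("pair48", phantom_pair(
  phantom_spec(grid_shape = c(48, 48, 48), rng_seed = 11)))

# 48^3 noiseless pair (exact-arithmetic checks)
pair48_clean <- function() fixture("pair48_clean", phantom_pair(
  phantom_spec(grid_shape = c(48, 48, 48), noise_sd_hu = 0, rng_seed = 12)))

# 32^3 lesioned pair for counting-exact oracle comparisons
pair32_lesioned <- function() fixture("pair32_lesioned", phantom_pair(
  phantom_spec(grid_shape = c(32, 32, 32), rng_seed = 13),
  lesions = lesion_spec(count = 2, radius_mm_range = c(0.08, 0.12))))

# five-animal basal cohort, analyzed end-to-end (real registration),
# plus the thresholds calibrated from it; reused by ventilation, cohort
# and acceptance tests
basal_cohort48 <- function() fixture("basal_cohort48", {
  cfg <- analysis_config()
  animals <- lapply(1:5, function(s) {
    pp <- phantom_pair(phantom_spec(grid_shape = c(48, 48, 48),
                                    rng_seed = 100 + s))
    rep <- analyze_scan_pair(pp$p01, pp$p02, cfg, thresholds = NULL,
                             mask_p01 = pp$mask_p01, mask_p02 = pp$mask_p02,
                             keep_maps = TRUE)
    list(pp = pp, rep = rep)
  })
  maps <- lapply(animals, function(a) a$rep$maps)
  list(animals = animals, maps = maps,
       thresholds = calibrate_thresholds(maps, c(5, 5, 25)))
})

# classify a phantom pair using its ground-truth displacement field
# (isolates the classifier from registration error)
classify_with_truth_field <- function(pp, thresholds, cfg = analysis_config()) {
  wp02 <- warp_volume(pp$p02, pp$field)
  wmask <- warp_volume(pp$mask_p02, pp$field)
  svg1 <- specific_gas_volume(pp$p01, pp$mask_p01,
                              cfg$tissue_specific_volume_ml_per_g,
                              cfg$hu_clip_range)
  svg2 <- specific_gas_volume(wp02, wmask,
                              cfg$tissue_specific_volume_ml_per_g,
                              cfg$hu_clip_range)
  dsv <- delta_svg(svg1, svg2)
  list(vent = classify_voxels(svg1, svg2, dsv, thresholds, pp$mask_p01),
       svg1 = svg1, svg2 = svg2, delta = dsv)
}

# --- oracles ---------------------------------------------------------------

oracle_mla <- function(values, labels, region_codes) {
  tot <- 0; n <- 0L
  for (i in seq_along(values)) {
    if (labels[i] %in% region_codes) { tot <- tot + values[i]; n <- n + 1L }
  }
  tot / n
}

oracle_compartments <- function(values, labels, region_codes,
                                b = c(-860, -435, -121, 121)) {
  counts <- c(normo = 0L, hypo = 0L, non = 0L, other = 0L)
  n <- 0L
  for (i in seq_along(values)) {
    if (!(labels[i] %in% region_codes)) next
    n <- n + 1L
    v <- values[i]
    if (v >= b[1] && v <= b[2]) counts["normo"] <- counts["normo"] + 1L
    else if (v > b[2] && v < b[3]) counts["hypo"] <- counts["hypo"] + 1L
    else if (v >= b[3] && v <= b[4]) counts["non"] <- counts["non"] + 1L
    else counts["other"] <- counts["other"] + 1L
  }
  100 * counts / n
}

oracle_classify <- function(svg_i, svg_e, dsv, th) {
  out <- integer(length(dsv))
  for (i in seq_along(dsv)) {
    if (is.na(dsv[i])) next
    if (dsv[i] >= th$beta) out[i] <- 1L
    else if (svg_i[i] < th$alpha_I && svg_e[i] < th$alpha_E) out[i] <- 3L
    else out[i] <- 2L
  }
  out
}

oracle_mean_sem <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  s <- sqrt(sum((v - m)^2) / (n - 1))
  list(mean = m, sem = s / sqrt(n), n = n)
}

mean_epe_voxels <- function(field_a, field_b, sel, spacing = 0.05) {
  e <- sqrt((field_a$vectors[, , , 1] - field_b$vectors[, , , 1])^2 +
            (field_a$vectors[, , , 2] - field_b$vectors[, , , 2])^2 +
            (field_a$vectors[, , , 3] - field_b$vectors[, , , 3])^2) / spacing
  mean(e[sel])
}
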