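# SVg maps, Delta-SVg, threshold calibration and the three-class voxel
# classifier.

svg_of_hu <- function(hu) {
  d <- c(8, 8, 8)
  ct <- ct_volume(array(hu, d), spacing_mm = 0.05, phase = "P01")
  mask <- lung_labels(array(1L, d), spacing_mm = 0.05)
  specific_gas_volume(ct, mask)$values[1]
}

test_that("SVg follows the printed formula and its analytic properties", {
  # 1000/500 - 1/1.065 = 1.061 ml/g
  expect_equal(svg_of_hu(-500), 1000 / 500 - 1 / 1.065, tolerance = 1e-12)
  expect_equal(round(svg_of_hu(-500), 3), 1.061)
  # zero crossing at HU = 1000 * 1.065 - 1000 = 65.0
  hu0 <- 1000 * 1.065 - 1000
  expect_lt(abs(svg_of_hu(hu0)), 1e-12)
  expect_gt(svg_of_hu(64), 0)
  expect_lt(svg_of_hu(66), 0)
  # strictly decreasing over the clipped range
  hus <- seq(-990, 1000, by = 10)
  svs <- vapply(hus, svg_of_hu, 0)
  expect_true(all(diff(svs) < 0))
  # clipping bounds the map below -990 HU
  expect_equal(svg_of_hu(-1000), svg_of_hu(-990))
  # defined only inside the lung
  d <- c(8, 8, 8)
  ct <- ct_volume(array(-500, d), spacing_mm = 0.05)
  mask <- lung_labels(array(0L, d), spacing_mm = 0.05)
  mask$labels[1:4, , ] <- 1L
  sm <- specific_gas_volume(ct, mask)
  expect_true(all(is.na(sm$values[5:8, , ])))
})

test_that("Delta-SVg is a masked subtraction on the mask intersection", {
  pp <- pair48_clean()
  svg1 <- specific_gas_volume(pp$p01, pp$mask_p01)
  expect_true(all(delta_svg(svg1, svg1)$values[svg1$mask] == 0))

  wp02 <- warp_volume(pp$p02, pp$field)
  wmask <- warp_volume(pp$mask_p02, pp$field)
  svg2 <- specific_gas_volume(wp02, wmask)
  dsv <- delta_svg(svg1, svg2)
  expect_identical(dsv$mask, svg1$mask & svg2$mask)
  expect_true(all(is.finite(dsv$values[dsv$mask])))
  # ventilating parenchyma holds more gas per gram at inspiration
  expect_gt(mean(dsv$values[dsv$mask]), 0)

  bad <- svg1; bad$values <- array(0, c(24, 48, 48))
  expect_error(delta_svg(svg1, bad), "mismatch")
})

test_that("calibration reduces to per-animal percentiles and their mean", {
  b <- basal_cohort48()
  one <- calibrate_thresholds(b$maps[1], c(5, 5, 25))
  m <- b$maps[[1]]
  dom <- m$delta$mask
  expect_equal(one$alpha_I, quantile(m$svg_p01$values[dom], 0.05, names = FALSE))
  expect_equal(one$alpha_E, quantile(m$svg_p02$values[dom], 0.05, names = FALSE))
  expect_equal(one$beta, quantile(m$delta$values[dom], 0.25, names = FALSE))

  # degenerate cohort of identical animals -> the common percentiles
  same <- calibrate_thresholds(b$maps[c(1, 1, 1)], c(5, 5, 25))
  expect_equal(same$alpha_I, one$alpha_I)
  expect_equal(same$beta, one$beta)

  # cohort mean of per-animal percentiles
  five <- calibrate_thresholds(b$maps, c(5, 5, 25))
  per_animal <- vapply(b$maps, function(m)
    quantile(m$delta$values[m$delta$mask], 0.25, names = FALSE), 0)
  expect_equal(five$beta, mean(per_animal))

  # pooled alternative differs in general but stays close here
  pooled <- calibrate_thresholds(b$maps, c(5, 5, 25), pooled = TRUE)
  expect_true(is.finite(pooled$beta))

  expect_error(calibrate_thresholds(list()), "empty")
  expect_error(calibrate_thresholds(list(list(svg_p01 = 1, svg_p02 = 2))),
               "Delta-SVg")
})

test_that("classification matches the three-condition table exactly", {
  # controlled maps: one voxel per case
  d <- c(4, 4, 4)
  mk <- function(vals) {
    m <- array(NA_real_, d); m[seq_along(vals)] <- vals
    structure(list(values = m, mask = !is.na(m), spacing_mm = rep(0.05, 3),
                   origin_mm = c(0, 0, 0), phase = "P01"), class = "svg_map")
  }
  th <- ventilation_thresholds(alpha_I = 1.0, alpha_E = 0.8, beta = 0.2)
  #           normal@beta  low     fib     mixed-I  mixed-E
  svg_i <- mk(c(1.5,        1.5,    0.5,    0.5,     1.5))
  svg_e <- mk(c(1.0,        1.0,    0.4,    1.0,     0.4))
  dv    <- c(0.2,           0.1,    0.1,    0.1,     0.1)
  delta <- structure(list(values = mk(dv)$values, mask = mk(dv)$mask,
                          spacing_mm = rep(0.05, 3), origin_mm = c(0, 0, 0)),
                     class = "delta_svg_map")
  mask <- lung_labels(array(c(rep(1L, 5), rep(0L, prod(d) - 5)), d),
                      spacing_mm = 0.05)
  out <- classify_voxels(svg_i, svg_e, delta, th, mask)
  expect_identical(out$class_map[1:5], c(1L, 2L, 3L, 2L, 2L))  # Delta == beta -> Normal
  s <- out$summary[out$summary$region == "whole", ]
  expect_equal(s$pct_normal_vent + s$pct_low_vent + s$pct_fibrosis, 100)

  sep <- classify_voxels(svg_i, svg_e, delta, th, mask, mixed_class = "separate")
  expect_identical(sep$class_map[1:5], c(1L, 2L, 3L, 4L, 4L))

  expect_error(classify_voxels(svg_i, svg_e, delta, list(beta = 1), mask),
               "calibrated")
})

test_that("classifier agrees voxel-for-voxel with the brute-force oracle", {
  b <- basal_cohort48()
  th <- b$thresholds
  pp <- pair32_lesioned()
  res <- classify_with_truth_field(pp, th)
  orac <- oracle_classify(res$svg1$values, res$svg2$values, res$delta$values, th)
  expect_identical(as.vector(res$vent$class_map), orac)
  # partition: every domain voxel classified, sums exact
  expect_identical(sum(res$vent$class_map > 0), sum(res$delta$mask))
  s <- res$vent$summary[1, ]
  expect_equal(s$pct_normal_vent + s$pct_low_vent + s$pct_fibrosis + s$pct_mixed,
               100, tolerance = 1e-9)
})

test_that("calibration is self-consistent on its own cohort", {
  b <- basal_cohort48()
  th <- b$thresholds
  expect_gt(th$beta, 0)
  fr_ai <- vapply(b$maps, function(m)
    mean(m$svg_p01$values[m$delta$mask] < th$alpha_I), 0)
  fr_b <- vapply(b$maps, function(m)
    mean(m$delta$values[m$delta$mask] < th$beta), 0)
  expect_lt(abs(mean(fr_ai) - 0.05), 0.03)
  expect_lt(abs(mean(fr_b) - 0.25), 0.05)
})

test_that("%Fibrosis responds monotonically to lesion burden", {
  b <- basal_cohort48()
  th <- b$thresholds
  spec <- phantom_spec(grid_shape = c(48, 48, 48), rng_seed = 31)
  anat <- generate_anatomy(spec)
  geom <- plant_lesions(anat$ct, anat$mask,
                        lesion_spec(count = 5, radius_mm_range = c(0.15, 0.3)),
                        seed = 32)
  fibs <- c(); fracs <- c()
  for (s in c(0.3, 0.5, 0.7, 0.85, 1.0)) {
    pl <- plant_lesions(anat$ct, anat$mask,
                        lesion_spec(count = 5), seed = 33,
                        centers = geom$centers, radii_mm = geom$radii_mm * s)
    set.seed(40)
    def <- apply_respiratory_deformation(pl$ct, anat$mask, deformation_model(),
                                         pl$lesion_labels,
                                         noise_sd_hu = spec$noise_sd_hu)
    p01 <- pl$ct
    p01$values <- pmin(pmax(p01$values +
      rnorm(length(p01$values), 0, spec$noise_sd_hu), -1000), 1000)
    pp <- list(p01 = p01, p02 = def$ct_exp, mask_p01 = anat$mask,
               mask_p02 = def$mask_exp, field = def$field)
    res <- classify_with_truth_field(pp, th)
    fibs <- c(fibs, res$vent$summary$pct_fibrosis[1])
    fracs <- c(fracs, sum(pl$lesion_labels) / sum(anat$mask$labels > 0))
  }
  expect_true(all(diff(fracs) > 0))
  expect_true(all(diff(fibs) >= 0))
  expect_gt(fibs[5], fibs[1])
})
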