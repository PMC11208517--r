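# Morphological biomarkers against closed forms and brute-force oracles.

uniform_lung <- function(hu, n = 12) {
  d <- c(n, n, n)
  lab <- array(0L, d)
  lab[3:(n - 2), 3:(n - 2), 3:(n - 2)] <- 1L
  lab[(n %/% 2):(n - 2), 3:(n - 2), 3:(n - 2)] <- 2L
  list(ct = ct_volume(array(hu, d), spacing_mm = 0.05),
       mask = lung_labels(lab, spacing_mm = 0.05))
}

test_that("mean lung attenuation matches arithmetic and the loop oracle", {
  u <- uniform_lung(-550)
  expect_equal(mean_lung_attenuation(u$ct, u$mask), -550)

  v <- uniform_lung(-600)
  sel <- which(v$mask$labels > 0)
  half <- sel[seq_len(length(sel) %/% 2)]
  v$ct$values[half] <- -400
  expect_equal(mean_lung_attenuation(v$ct, v$mask), -500)

  pp <- pair32_lesioned()
  for (reg in list(c("whole", 1, 2), c("left", 1), c("right", 2))) {
    expect_equal(
      mean_lung_attenuation(pp$p01, pp$mask_p01, reg[1]),
      oracle_mla(pp$p01$values, pp$mask_p01$labels, as.integer(reg[-1])))
  }
  empty <- lung_labels(array(0L, dim(u$ct$values)), spacing_mm = 0.05)
  expect_error(mean_lung_attenuation(u$ct, empty), "empty")
})

test_that("lung volume is voxel count times voxel volume and additive", {
  d <- c(20, 20, 20)
  lab <- array(0L, d)
  lab[seq_len(1000)] <- 1L
  m <- lung_labels(lab, spacing_mm = 0.05)
  expect_equal(lung_volume(m, "left"), 1000 * 0.05^3)  # 0.125 mm^3
  expect_equal(lung_volume(m, "right"), 0)
  pp <- pair48()
  expect_identical(lung_volume(pp$mask_p01, "whole"),
                   lung_volume(pp$mask_p01, "left") +
                     lung_volume(pp$mask_p01, "right"))
})

test_that("aeration boundaries follow the closed/open bracket conventions", {
  probe <- function(hu) {
    u <- uniform_lung(hu)
    aeration_compartments(u$ct, u$mask)
  }
  expect_equal(unname(probe(-600)), c(100, 0, 0, 0))
  expect_equal(unname(probe(-435)[["pct_normo"]]), 100)  # closed upper Normo
  expect_equal(unname(probe(-434.99)[["pct_hypo"]]), 100)
  expect_equal(unname(probe(-121)[["pct_non"]]), 100)    # closed lower Non
  expect_equal(unname(probe(-121.01)[["pct_hypo"]]), 100)
  expect_equal(unname(probe(-860)[["pct_normo"]]), 100)  # closed lower Normo
  expect_equal(unname(probe(-860.01)[["pct_other"]]), 100) # hyper-aerated
  expect_equal(unname(probe(121.01)[["pct_other"]]), 100)
})

test_that("compartment percentages sum to 100 and are HU-shift invariant", {
  set.seed(42)
  for (i in 1:5) {
    d <- c(16, 16, 16)
    ct <- ct_volume(array(runif(prod(d), -1000, 300), d), spacing_mm = 0.05)
    lab <- array(sample(0:2, prod(d), TRUE), d)
    mask <- lung_labels(lab, spacing_mm = 0.05)
    comp <- aeration_compartments(ct, mask)
    expect_equal(sum(comp), 100, tolerance = 1e-9)
    shift <- 57.3
    ct2 <- ct; ct2$values <- ct$values + shift
    comp2 <- aeration_compartments(ct2, mask,
                                   boundaries_hu = c(-860, -435, -121, 121) + shift)
    expect_identical(comp, comp2)
  }
})

test_that("planted lesion fraction is recovered as %Non on truth masks", {
  # non-overlapping HU distributions: parenchyma inside Normo, lesion inside Non
  spec <- phantom_spec(grid_shape = c(48, 48, 48), parenchyma_hu_sd = 20,
                       noise_sd_hu = 0, rng_seed = 21)
  pp <- phantom_pair(spec,
                     lesions = lesion_spec(count = 3, hu_mean = 20, hu_sd = 20,
                                           radius_mm_range = c(0.12, 0.2)))
  f <- pp$truth$lesion_fraction
  expect_gt(f, 0.01)
  comp <- aeration_compartments(pp$p01, pp$mask_p01)
  expect_lt(abs(comp[["pct_non"]] - 100 * f), 0.5)
})

test_that("gas/tissue decomposition matches its closed forms", {
  expect_equal(unname(gas_tissue_decomposition(uniform_lung(-1000)$ct,
                                               uniform_lung(-1000)$mask)["pct_gas"]), 100)
  expect_equal(unname(gas_tissue_decomposition(uniform_lung(0)$ct,
                                               uniform_lung(0)$mask)["pct_gas"]), 0)
  u <- uniform_lung(-600)
  g <- gas_tissue_decomposition(u$ct, u$mask)
  expect_equal(unname(g["pct_gas"]), 60)
  expect_equal(unname(g["gas_volume_mm3"] + g["tissue_volume_mm3"]),
               lung_volume(u$mask), tolerance = 1e-12)
})

test_that("tidal volume is the phase volume difference, additive by side", {
  pp <- pair48()
  expect_equal(tidal_volume(pp$mask_p01, pp$mask_p01), 0)
  expect_gt(tidal_volume(pp$mask_p01, pp$mask_p02), 0)  # compression
  expect_equal(tidal_volume(pp$mask_p01, pp$mask_p02, "whole"),
               tidal_volume(pp$mask_p01, pp$mask_p02, "left") +
                 tidal_volume(pp$mask_p01, pp$mask_p02, "right"))
})

test_that("compartments agree voxel-for-voxel with the brute-force oracle", {
  pp <- pair32_lesioned()
  for (reg in list(list("whole", c(1L, 2L)), list("left", 1L), list("right", 2L))) {
    mine <- aeration_compartments(pp$p01, pp$mask_p01, reg[[1]])
    orac <- oracle_compartments(pp$p01$values, pp$mask_p01$labels, reg[[2]])
    expect_equal(unname(mine), unname(orac))
  }
  # whole equals the voxel-weighted combination of left and right
  nl <- sum(pp$mask_p01$labels == 1L); nr <- sum(pp$mask_p01$labels == 2L)
  ml <- mean_lung_attenuation(pp$p01, pp$mask_p01, "left")
  mr <- mean_lung_attenuation(pp$p01, pp$mask_p01, "right")
  expect_equal(mean_lung_attenuation(pp$p01, pp$mask_p01, "whole"),
               (nl * ml + nr * mr) / (nl + nr))
})
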