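# Synthetic thorax phantom: anatomy, lesions, mass-conserving deformation,
# cohort simulation.

test_that("anatomy honours degenerate and stochastic parenchyma settings", {
  spec0 <- phantom_spec(grid_shape = c(32, 32, 32), noise_sd_hu = 0,
                        parenchyma_hu_sd = 0, rng_seed = 1)
  a0 <- generate_anatomy(spec0)
  expect_true(all(a0$ct$values[a0$mask$labels > 0] == -550))
  expect_true(all(a0$ct$values[a0$mask$labels == 0] %in% c(-1000, 40)))
  expect_gt(sum(a0$mask$labels == 1L), 0)
  expect_identical(sum(a0$mask$labels == 1L), sum(a0$mask$labels == 2L))

  spec <- phantom_spec(grid_shape = c(48, 48, 48), rng_seed = 5)
  a <- generate_anatomy(spec)
  hu <- a$ct$values[a$mask$labels > 0]
  expect_lt(abs(mean(hu) + 550), 3 * 45 / sqrt(length(hu)))

  b <- generate_anatomy(spec)
  expect_identical(a$ct$values, b$ct$values)  # bit-identical under seed

  expect_error(generate_anatomy(phantom_spec(grid_shape = c(31, 64, 64))),
               "grid too small")
  expect_error(phantom_spec(body_hu = 2000), "HU parameters")
})

test_that("lesion planting is identity at count 0 and exact at sd 0", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), noise_sd_hu = 0, rng_seed = 2)
  a <- generate_anatomy(spec)
  l0 <- plant_lesions(a$ct, a$mask, lesion_spec(count = 0))
  expect_identical(l0$ct$values, a$ct$values)
  expect_false(any(l0$lesion_labels))

  l1 <- plant_lesions(a$ct, a$mask,
                      lesion_spec(count = 1, radius_mm_range = c(0.1, 0.1),
                                  hu_mean = 20, hu_sd = 0), seed = 3)
  expect_gt(sum(l1$lesion_labels), 0)
  expect_true(all(l1$ct$values[l1$lesion_labels] == 20))
  # lesions are a subset of the lung
  expect_true(all(a$mask$labels[l1$lesion_labels] > 0))
  # infeasible request
  expect_error(plant_lesions(a$ct, a$mask,
                             lesion_spec(count = 40,
                                         radius_mm_range = c(0.5, 0.6)),
                             seed = 3),
               "infeasible|lung extent")
  expect_error(lesion_spec(hu_mean = -400), "-121")
})

test_that("mass-conserving intensity rule matches its closed form", {
  expect_equal(lungct:::hu_mass_transform(-500, 0.75), 500 / 0.75 - 1000,
               tolerance = 1e-12)  # -333.33 HU
  expect_equal(lungct:::hu_mass_transform(-1000, 0.6), -1000)  # gas is massless
  expect_equal(lungct:::hu_mass_transform(0, 1), 0)
})

test_that("zero-amplitude deformation is the identity with unit Jacobian", {
  spec <- phantom_spec(grid_shape = c(32, 32, 32), noise_sd_hu = 0, rng_seed = 4)
  a <- generate_anatomy(spec)
  d <- apply_respiratory_deformation(a$ct, a$mask,
                                     deformation_model(amplitude_mm = 0))
  expect_identical(d$ct_exp$values, a$ct$values)
  expect_true(all(d$jacobian == 1))
  expect_true(all(d$field$vectors == 0))
})

test_that("deformed phantoms conserve tissue mass and lose gas volume", {
  pp <- pair48_clean()
  vv <- prod(pp$p01$spacing_mm)
  mass <- function(ct, mask) sum((ct$values[mask$labels > 0] + 1000) / 1000) * vv
  m_in <- mass(pp$p01, pp$mask_p01)
  m_ex <- mass(pp$p02, pp$mask_p02)
  expect_lt(abs(m_in - m_ex) / m_in, 0.01)

  g_in <- gas_tissue_decomposition(pp$p01, pp$mask_p01)[["gas_volume_mm3"]]
  g_ex <- gas_tissue_decomposition(pp$p02, pp$mask_p02)[["gas_volume_mm3"]]
  expect_lt(g_ex, g_in)
  # compression also shrinks the segmented lung
  expect_lt(lung_volume(pp$mask_p02), lung_volume(pp$mask_p01))
})

test_that("phantom truth bundle is internally consistent", {
  pp <- pair32_lesioned()
  for (fr in pp$truth$compartment_fractions)
    expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_true(all(pp$mask_p01$labels[pp$lesion_labels] > 0))
  expect_true(all(pp$jacobian > 0))
  # non-invertible request errors
  spec <- phantom_spec(grid_shape = c(32, 32, 32), noise_sd_hu = 0, rng_seed = 1)
  a <- generate_anatomy(spec)
  expect_error(apply_respiratory_deformation(
    a$ct, a$mask, deformation_model(amplitude_mm = 5, smoothness_mm = 3)),
    "non-invertible")
})

test_that("cohort simulation writes a deterministic, truthful manifest", {
  plan <- cohort_plan(n_subjects = 1, groups = c("SAL", "BLM"),
                      timepoints_days = c(0, 14, 28),
                      treatment_start_day = list(), rng_seed = 9)
  spec <- phantom_spec(grid_shape = c(48, 48, 48), rng_seed = 9)
  les <- lesion_spec(count = 3, radius_mm_range = c(0.15, 0.25))
  d1 <- file.path(tempdir(), "cohortA")
  d2 <- file.path(tempdir(), "cohortB")
  man1 <- simulate_cohort(plan, spec, d1, les)
  man2 <- simulate_cohort(plan, spec, d2, les)
  expect_identical(man1[, c("subject_id", "group", "day")],
                   man2[, c("subject_id", "group", "day")])
  expect_equal(nrow(man1), 6)  # 2 subjects x 3 days
  expect_true(all(file.exists(man1$p01_path)))

  # volumes are bit-identical across the two runs
  v1 <- read_volume(man1$p01_path[1])
  v2 <- read_volume(man2$p01_path[1])
  expect_identical(v1$values, v2$values)

  lesion_frac <- function(row) {
    lab <- lungct:::read_nifti_array(paste0(row$truth_prefix, "_lesions.nii.gz"))$data
    mask <- read_labels(row$mask_path)
    sum(lab > 0) / sum(mask$labels > 0)
  }
  sal <- man1[man1$group == "SAL", ]
  blm <- man1[man1$group == "BLM", ]
  blm <- blm[order(blm$day), ]
  for (i in seq_len(nrow(sal))) expect_equal(lesion_frac(sal[i, ]), 0)
  fr <- vapply(seq_len(nrow(blm)), function(i) lesion_frac(blm[i, ]), 0)
  expect_equal(fr[1], 0)          # day 0 lesion-free
  expect_true(all(diff(fr) >= 0)) # burden non-decreasing
  expect_gt(fr[length(fr)], 0)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("cohort plan enforces its scheduling invariants", {
  expect_error(cohort_plan(timepoints_days = c(7, 14)), "day 0")
  expect_error(cohort_plan(groups = c("SAL", "NINT_7_28"),
                           timepoints_days = c(0, 14, 28),
                           treatment_start_day = list(NINT_7_28 = 9)),
               "timepoints")
  plan <- cohort_plan(groups = c("SAL", "BLM", "NINT_14_28"),
                      timepoints_days = c(0, 7, 14, 21, 28))
  sev_blm <- vapply(c(0, 7, 14, 21, 28), function(d)
    lungct:::lesion_severity(plan, "BLM", d), 0)
  sev_trt <- vapply(c(0, 7, 14, 21, 28), function(d)
    lungct:::lesion_severity(plan, "NINT_14_28", d), 0)
  expect_true(all(diff(sev_blm) > 0))
  expect_true(all(diff(sev_trt) >= 0))
  expect_true(all(sev_trt[4:5] < sev_blm[4:5]))  # attenuation after day 14
  expect_equal(sev_trt[1:3], sev_blm[1:3])       # identical before treatment
})
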