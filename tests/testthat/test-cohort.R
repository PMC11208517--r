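# Scan-pair orchestration, fold-changes and cohort tables.

mock_report <- function(day, pct_normo, pct_non, pct_fib = 0) {
  aer <- do.call(rbind, lapply(c("whole", "left", "right"), function(r)
    data.frame(region = r, phase = c("P01", "P02"),
               volume_mm3 = 3, mla_hu = -500, pct_normo = pct_normo,
               pct_hypo = 100 - pct_normo - pct_non, pct_non = pct_non,
               pct_other = 0, gas_volume_mm3 = 1.5, tissue_volume_mm3 = 1.5,
               pct_gas = 50, stringsAsFactors = FALSE)))
  vent <- data.frame(region = c("whole", "left", "right"), n_voxels = 100,
                     pct_normal_vent = 80, pct_low_vent = 20 - pct_fib,
                     pct_fibrosis = pct_fib, pct_mixed = 0,
                     stringsAsFactors = FALSE)
  structure(list(subject_id = "s1", day = day, aeration = aer,
                 tidal = data.frame(region = c("whole", "left", "right"),
                                    tidal_volume_mm3 = 0.2),
                 ventilation = vent, qc_flags = character(0)),
            class = "subject_timepoint_report")
}

test_that("a clean baseline pair analyzes without QC flags", {
  b <- basal_cohort48()
  pp <- b$animals[[1]]$pp
  rep <- analyze_scan_pair(pp$p01, pp$p02, analysis_config(),
                           thresholds = b$thresholds,
                           mask_p01 = pp$mask_p01, mask_p02 = pp$mask_p02)
  expect_length(rep$qc_flags, 0)
  aer <- rep$aeration
  expect_lt(max(aer$pct_non), 2)  # clean phantom, by construction
  expect_false(is.null(rep$ventilation))
  # determinism
  rep2 <- analyze_scan_pair(pp$p01, pp$p02, analysis_config(),
                            thresholds = b$thresholds,
                            mask_p01 = pp$mask_p01, mask_p02 = pp$mask_p02)
  expect_identical(rep$aeration, rep2$aeration)
  expect_identical(rep$ventilation, rep2$ventilation)
})

test_that("stage failures propagate as QC flags with metrics absent", {
  d <- c(40, 40, 40)
  empty1 <- ct_volume(array(-1000, d), spacing_mm = 0.05, phase = "P01")
  empty2 <- ct_volume(array(-1000, d), spacing_mm = 0.05, phase = "P02")
  rep <- analyze_scan_pair(empty1, empty2, analysis_config())
  expect_true("segmentation-failure" %in% rep$qc_flags)
  expect_null(rep$aeration)
  expect_null(rep$ventilation)
})

test_that("thresholds absent is flagged, functional metrics omitted", {
  pp <- pair32_lesioned()
  cfg <- analysis_config()
  cfg$registration <- registration_params(n_levels = 2,
                                          iterations_per_level = c(30, 15))
  rep <- analyze_scan_pair(pp$p01, pp$p02, cfg, thresholds = NULL,
                           mask_p01 = pp$mask_p01, mask_p02 = pp$mask_p02)
  expect_true("thresholds-absent" %in% rep$qc_flags)
  expect_null(rep$ventilation)
  expect_false(is.null(rep$aeration))
})

test_that("fold changes reduce to self-ratios at day 0 and simple ratios later", {
  reports <- list(mock_report(0, 80, 2), mock_report(14, 40, 10, pct_fib = 8))
  fc <- fold_change_vs_baseline(reports, subject_id = "s1", group = "BLM")
  d0 <- fc[fc$day == 0 & fc$region == "whole", ]
  expect_true(all(d0$fold_change[!d0$metric %in% "pct_fibrosis"] == 1))
  d14 <- fc[fc$day == 14 & fc$region == "whole", ]
  expect_equal(d14$fold_change[d14$metric == "pct_normo"], 0.5)
  expect_equal(d14$fold_change[d14$metric == "pct_non"], 5)
  # fibrosis stays raw
  expect_true(all(is.na(fc$fold_change[fc$metric == "pct_fibrosis"])))
  expect_equal(fc$value[fc$metric == "pct_fibrosis" & fc$day == 14 &
                          fc$region == "whole"], 8)
  expect_error(fold_change_vs_baseline(list(mock_report(14, 40, 10))),
               "day-0")
})

test_that("group summaries match the textbook formulas", {
  tab <- data.frame(group = "BLM", day = 14, region = "whole",
                    metric = "pct_normo", value = c(1, 2, 3),
                    baseline_value = 1, fold_change = c(1, 2, 3))
  s <- summarize_group(tab, "BLM", 14, "pct_normo")
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3))
  expect_equal(s$n, 3)

  one <- summarize_group(tab[1, ], "BLM", 14, "pct_normo")
  expect_true(is.na(one$sem)); expect_equal(one$n, 1)
  onez <- summarize_group(tab[1, ], "BLM", 14, "pct_normo",
                          sem_single = "zero")
  expect_equal(onez$sem, 0)

  set.seed(8)
  for (i in 1:5) {
    v <- rnorm(sample(3:12, 1))
    tabr <- data.frame(group = "g", day = 1, region = "whole", metric = "m",
                       value = v, baseline_value = 1, fold_change = v)
    s <- summarize_group(tabr, "g", 1, "m")
    o <- oracle_mean_sem(v)
    expect_equal(s$mean, o$mean)
    expect_equal(s$sem, o$sem)
  }
  expect_error(summarize_group(tab, "SAL", 14, "pct_normo"), "no observations")
})

test_that("run_cohort aborts on missing files, listing them", {
  man <- data.frame(subject_id = "x1", group = "SAL", day = 0,
                    p01_path = "/nonexistent/a.nii.gz",
                    p02_path = "/nonexistent/b.nii.gz",
                    stringsAsFactors = FALSE)
  expect_error(run_cohort(man, analysis_config(), tempfile()),
               "missing files.*a\\.nii\\.gz")
})
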