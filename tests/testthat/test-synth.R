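test_that("cohort generation is deterministic given the seed", {
  cfg <- ba_only_cfg(seed = 42, n_con = 2, n_ls = 2)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1$subjects$CON01$scans$F1$voxels,
                   co2$subjects$CON01$scans$F1$voxels)
  expect_identical(co1$subjects$LS02$scans$F3$voxels,
                   co2$subjects$LS02$scans$F3$voxels)
  expect_identical(co1$subjects$CON02$traces$F3$scores,
                   co2$subjects$CON02$traces$F3$scores)
  co3 <- generate_cohort(synth_config(
    grid_shape = cfg$grid_shape, n_con = 2, n_ls = 2,
    region_specs = cfg$region_specs, effect_map = cfg$effect_map,
    sd_subject = cfg$sd_subject, sd_hemisphere = cfg$sd_hemisphere,
    sd_slice = cfg$sd_slice, sd_voxel = cfg$sd_voxel, seed = 43))
  expect_false(identical(co1$subjects$CON01$scans$F1$voxels,
                         co3$subjects$CON01$scans$F1$voxels))
})

test_that("zero-noise cohorts reproduce planted increments exactly downstream", {
  co <- generate_cohort(zero_noise_cfg(seed = 7), traces = FALSE)
  d <- cohort_delta_table(co)
  eff <- default_effect_map()
  for (grp in c("CON", "LS")) {
    dg <- d[grepl(paste0("^", grp), d$subject), ]
    for (rg in names(eff[[grp]])) {
      expect_equal(dg$delta_suv[dg$region == rg],
                   rep(eff[[grp]][[rg]], sum(dg$region == rg)),
                   tolerance = 1e-10)
    }
  }
})

test_that("null planted effects give cohort-mean delta-SUV near zero", {
  cfg <- ba_only_cfg(seed = 99, n_con = 10, n_ls = 10, eff_con = 0, eff_ls = 0)
  co <- generate_cohort(cfg, traces = FALSE)
  d <- cohort_delta_table(co)
  m <- subject_region_mean(d)
  se <- sd(m$mean_delta) / sqrt(nrow(m))
  expect_lt(abs(mean(m$mean_delta)), 3 * se)
})

test_that("per-slice delta-SUV variance grows with each noise SD", {
  base <- list(sd_subject = 0.01, sd_hemisphere = 0.01, sd_slice = 0.01,
               sd_voxel = 0.05)
  record_var <- function(sds) {
    cfg <- do.call(ba_only_cfg, c(list(seed = 5, n_con = 6, n_ls = 2,
                                       eff_con = 0, eff_ls = 0), sds))
    var(cohort_delta_table(generate_cohort(cfg, traces = FALSE))$delta_suv)
  }
  v0 <- record_var(base)
  for (nm in names(base)) {
    up <- base
    up[[nm]] <- base[[nm]] * 6
    expect_gt(record_var(up), v0)
  }
})

test_that("activity traces hit degenerate freezing targets exactly", {
  thr <- activity_threshold_default()
  tr1 <- generate_activity_trace(list(freezing_frac = 1, mean_bout_s = 5,
                                      bout_cv = 1), 10, 60, seed = 1)
  expect_true(all(tr1$scores < thr))
  tr0 <- generate_activity_trace(list(freezing_frac = 0, mean_bout_s = 5,
                                      bout_cv = 1), 10, 60, seed = 1)
  expect_true(all(tr0$scores > thr))
  expect_length(tr0$scores, 600)
  expect_error(generate_activity_trace(list(freezing_frac = 0.5,
                                            mean_bout_s = -1, bout_cv = 1),
                                       10, 60), "mean_bout_s")
})

test_that("empirical freezing fraction is unbiased for the target", {
  f <- vapply(1:1000, function(i) {
    tr <- generate_activity_trace(list(freezing_frac = 0.45, mean_bout_s = 5,
                                       bout_cv = 1), 10, 480, seed = 10000 + i)
    mean(binarize_activity(tr)$inactive)
  }, 0)
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - 0.45), 3 * se)
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(synth_config(n_con = 0), "n_con")
  expect_error(synth_config(sd_voxel = -1), "sd_voxel")
  expect_error(synth_config(region_specs = list(
    list(region = "BA", slices = 1:40, bilateral = TRUE,
         x_left = c(8, 10), x_right = c(23, 25), y = c(18, 22)))),
    "slices outside grid")
  expect_error(synth_config(effect_map = list(CON = c(BA = 0.1),
                                              LS = c(BA = 0))),
               "effect_map")
})

test_that("fixtures round-trip through disk and the manifest validates", {
  co <- generate_cohort(ba_only_cfg(seed = 3, n_con = 2, n_ls = 2))
  dir <- withr::local_tempdir()
  manifest <- write_fixtures(co, dir)
  vol_files <- Filter(function(f) f$kind == "volume", manifest$files)
  expect_length(vol_files, 2 * length(co$subjects))
  for (su in names(co$subjects)) {
    ss <- vapply(Filter(function(f) f$kind == "volume" && f$subject == su,
                        manifest$files), `[[`, "", "session")
    expect_setequal(ss, c("F1", "F3"))
  }
  back <- read_fixtures(dir)
  v0 <- co$subjects$CON01$scans$F1$voxels
  v1 <- back$subjects$CON01$scans$F1$voxels
  expect_equal(v1, v0, tolerance = 1e-6)  # float32 storage
  expect_identical(back$labels[["LS02"]], "LS")
  d0 <- cohort_delta_table(co)
  co_rt <- co
  for (s in names(co_rt$subjects)) co_rt$subjects[[s]]$scans <- back$subjects[[s]]$scans
  co_rt$masks <- back$masks
  co_rt$brain_mask <- back$brain_mask
  d1 <- cohort_delta_table(co_rt)
  expect_equal(d1$delta_suv, d0$delta_suv, tolerance = 1e-5)
  file.remove(file.path(dir, "volumes", "CON01_F3.nii"))
  expect_error(validate_manifest(dir), "CON01.*F3")
})
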