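test_that("minimal shorthand config expands to the full default session", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("fluence_rate: 50", "time: 600", "BPD: 0.53"), f)
  s <- load_session(f)
  expect_equal(s$fluence_rate, 50)
  expect_equal(s$time_s, 600)
  expect_equal(s$bpd_uM, 0.53)
  expect_equal(s$optics$mu_a, 0.69)
  expect_equal(s$optics$mu_s_prime, 11)
  expect_equal(s$optics$n, 1.4)
  expect_equal(s$pk$O2_initial, 40)
  expect_equal(s$pk$g, 1.7)
  expect_equal(s$grid$voxel_cm, 0.05)
  expect_equal(s$grid$nx, 100)
  expect_equal(s$source$diameter_cm, 1)
})

test_that("structured JSON configs round-trip and validate", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    group = 9,
    source = list(fluence_rate = 75, diameter_mm = 10),
    grid = list(n = 40, voxel_mm = 0.5),
    optics = list(mu_a = 0.5),
    pk = list(S0_init_uM = 0.84, time_s = 2000, O2_init_uM = 35),
    mc = list(n_photons = 1e5, seed = 7)), f, auto_unbox = TRUE)
  s <- load_session(f)
  expect_equal(s$group_id, 9)
  expect_equal(s$fluence_rate, 75)
  expect_equal(s$optics$mu_a, 0.5)
  expect_equal(s$optics$mu_s_prime, 11)  # default preserved
  expect_equal(s$pk$O2_initial, 35)
  expect_equal(s$mc$seed, 7)
  expect_equal(s$grid$nx, 40)
})

test_that("config validation names the offending field", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("fluence_rate: 50", "time: 600"), f)
  expect_error(load_session(f), "S0_init_uM")
  writeLines(c("time: 600", "BPD: 0.5"), f)
  expect_error(load_session(f), "fluence_rate")
  expect_error(load_session("nope.yaml"), "not found")
})

test_that("inconsistent incident fluence triggers a warning", {
  expect_warning(treatment_session(50, 600, 0.53, fluence_J_cm2 = 40),
                 "differs")
  expect_silent(treatment_session(50, 600, 0.53, fluence_J_cm2 = 30))
  # printed group table is internally consistent within rounding
  tab <- bpd_mouse_groups()
  treated <- tab[tab$fluence_rate_mW_cm2 > 0, ]
  expect_true(all(abs(treated$fluence_rate_mW_cm2 * treated$time_s / 1000 -
                        treated$fluence_J_cm2) / treated$fluence_J_cm2 < 0.01))
})

test_that("pipeline runs are deterministic under a fixed seed", {
  s <- treatment_session(50, 600, 0.53, n_voxels = 24, n_photons = 2e4,
                         seed = 9)
  r1 <- run_pipeline(s)
  r2 <- run_pipeline(s)
  expect_identical(r1$dose_3mm_mM, r2$dose_3mm_mM)
  expect_identical(r1$fluence$values, r2$fluence$values)
  r3 <- run_pipeline(s, seed = 10)
  expect_false(identical(r1$dose_3mm_mM, r3$dose_3mm_mM))
})

test_that("control sessions (no light or no drug) give zero dose", {
  s15 <- group_session(15, voxel_mm = 0.5)
  rep <- run_pipeline(s15, full_map = TRUE)
  expect_true(all(rep$dose$values == 0))
  expect_equal(rep$dose_3mm_mM, 0)
  # light but no sensitizer
  s <- treatment_session(50, 600, 0, n_voxels = 20, n_photons = 2e4)
  expect_equal(run_pipeline(s)$dose_3mm_mM, 0)
})

test_that("batch runs share transport across equal-rate groups", {
  out <- run_batch(groups = c(1, 4), voxel_mm = 0.5, n_photons = 5e4,
                   seed = 3)
  expect_equal(nrow(out), 2)
  expect_true(all(c("group", "dose_3mm_mM", "reference_dose_mM")
                  %in% names(out)))
  expect_true(all(out$dose_3mm_mM > 0))
  # group 4 delivers more dose than group 1 (same rate, longer treatment)
  expect_gt(out$dose_3mm_mM[2], out$dose_3mm_mM[1])
})

test_that("NRRD volumes round-trip bit-exactly", {
  v <- array(rnorm(4 * 5 * 6), dim = c(4, 5, 6))
  f <- withr::local_tempfile(fileext = ".nrrd")
  write_nrrd(v, f, voxel_cm = 0.05)
  back <- read_nrrd(f)
  expect_identical(back$values, v)
  expect_equal(back$voxel_cm, 0.05)
})

test_that("NIfTI export carries the voxel spacing", {
  v <- array(runif(8 * 8 * 8), dim = c(8, 8, 8))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume_nifti(v, f, voxel_cm = 0.025)
  img <- RNifti::readNifti(f)
  expect_equal(dim(img), c(8, 8, 8))
  expect_equal(RNifti::pixdim(img), rep(0.25, 3))  # mm
  expect_equal(as.array(img), v, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("pipeline report files are written and consistent", {
  s <- treatment_session(50, 600, 0.53, n_voxels = 20, n_photons = 2e4,
                         seed = 2)
  dir <- withr::local_tempdir()
  rep <- run_pipeline(s, full_map = TRUE, out_dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("fluence.nrrd", "dose.nrrd", "profile.csv", "report.json")))))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$dose_3mm_mM, rep$dose_3mm_mM, tolerance = 1e-12)
  prof <- read.csv(file.path(dir, "profile.csv"))
  expect_equal(nrow(prof), 20)
  vol <- read_nrrd(file.path(dir, "dose.nrrd"))
  expect_identical(vol$values, rep$dose$values)
})
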