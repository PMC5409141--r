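# Containers, file round trips, config validation, session persistence.

test_that("ct_volume validates geometry and warns on implausible HU", {
  expect_error(ct_volume(matrix(0, 2, 2)), "3D")
  expect_error(ct_volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "spacing")
  expect_error(ct_volume(array(c(NA, rep(0, 7)), c(2, 2, 2))), "finite")
  expect_warning(ct_volume(array(5000, c(2, 2, 2))), "plausible")
  expect_silent(ct_volume(array(5000, c(2, 2, 2)), check_range = FALSE))
})

test_that("masks must match the reference grid and support set algebra", {
  v <- flat_volume(c(4, 4, 4), 0)
  m1 <- voxel_mask(array(TRUE, c(4, 4, 4)), v, "a")
  expect_error(voxel_mask(array(TRUE, c(4, 4, 3)), v), "shape")
  m2 <- array(FALSE, c(4, 4, 4)); m2[1:2, , ] <- TRUE
  expect_equal(sum(mask_intersect(m1, m2)), 32)
  expect_equal(sum(mask_diff(m1, m2)), 32)
  expect_equal(sum(mask_union(m1, m2)), 64)
  expect_equal(mask_volume_mm3(m1), 64)
  expect_equal(dice(m2, m2), 1)
})

test_that("NIfTI and MetaImage round trips preserve values and spacing", {
  ph <- generate_thigh_phantom(phantom_spec(dim = c(40, 40, 8), n_legs = 1,
                                            leg_radius = 18, sat_thickness = 6,
                                            femur_radius = 4, pat_thickness = 1,
                                            water_insert_radius = 0,
                                            acetabulum_slice = 1))
  for (ext in c("nii.gz", "mha", "mhd")) {
    path <- file.path(tempdir(), paste0("vol.", ext))
    write_volume(ph$volume, path)
    back <- read_volume(path)
    expect_equal(back$spacing, ph$volume$spacing, tolerance = 1e-6)
    # float32 storage precision
    expect_lt(max(abs(back$data - ph$volume$data)), 1e-3)
  }
})

test_that("a hand-built DICOM series maps raw values through slope/intercept", {
  dir <- file.path(tempdir(), "dcm")
  dir.create(dir, showWarnings = FALSE)
  raw1 <- matrix(as.integer(seq(0, 4095, length.out = 6 * 4)), 6, 4)
  raw2 <- matrix(as.integer(rev(seq(0, 4095, length.out = 6 * 4))), 6, 4)
  write_test_dicom_slice(file.path(dir, "s1.dcm"), raw1, z = 0,
                         slope = 2, intercept = -1024)
  write_test_dicom_slice(file.path(dir, "s2.dcm"), raw2, z = 2.5,
                         slope = 2, intercept = -1024)
  vol <- read_volume(dir)
  expect_equal(dim(vol$data), c(6, 4, 2))
  expect_equal(vol$data[, , 1], raw1 * 2 - 1024)
  expect_equal(vol$data[, , 2], raw2 * 2 - 1024)
  expect_equal(vol$spacing, c(0.8, 0.9, 2.5))
})

test_that("config: defaults, overrides, and range rejection", {
  empty <- file.path(tempdir(), "empty.json")
  writeLines("", empty)
  expect_equal(load_config(empty), load_config())
  over <- load_config(overrides = list(shielding_frac = 0.5))
  expect_equal(over$shielding_frac, 0.5)
  expect_error(load_config(overrides = list(shielding_frac = 1.5)),
               "permissible range")
  expect_error(load_config(overrides = list(nonsense = 1)), "unknown")
  jf <- file.path(tempdir(), "cfg.json")
  jsonlite::write_json(list(depth_min = 7), jf, auto_unbox = TRUE)
  expect_equal(load_config(jf)$depth_min, 7)
})

test_that("the operator grade is restricted to 1..3", {
  expect_error(mls_session(grade = 4), "1, 2 or 3")
  expect_error(mls_session(grade = 0), "1, 2 or 3")
  expect_error(grade_params(4), "range")
})

test_that("seed sets are bounds-checked and sessions survive JSON", {
  expect_error(seed_set(rbind(c(50, 1, 1)), "gap", c(10, 10, 10)), "outside")
  expect_error(seed_set(rbind(c(1, 1, 1)), "banana"), "role")
  ses <- mls_session(grade = 3,
                     seeds = seed_set(rbind(c(1, 2, 3), c(4, 5, 6)),
                                      c("gap", "reject")),
                     proximal_slice = 2, n_slices = 10, ct_h2o = -1.5,
                     config = load_config(overrides = list(depth_min = 8)))
  path <- file.path(tempdir(), "session.json")
  write_session(ses, path)
  back <- read_session(path)
  expect_equal(back$grade, 3L)
  expect_equal(back$seeds, ses$seeds)
  expect_equal(back$ct_h2o, -1.5)
  expect_equal(back$n_slices, 10L)
  expect_equal(back$config$depth_min, 8)
})
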