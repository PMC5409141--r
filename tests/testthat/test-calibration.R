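# Adipose reference, contrast scale, trimmed SAT threshold, T_HDM.

test_that("CT_AT is exact on a noiseless phantom and within 3 SE with noise", {
  ph0 <- generate_thigh_phantom(small_spec(noise_sd = 0, edema_count = 0))
  s0 <- segment_thigh_surface(ph0$volume, truth_mask(ph0, "femur"))
  at0 <- estimate_ct_at(ph0$volume, s0$sphere)
  expect_equal(at0$ct_at, -100)
  ph <- small_phantom()
  s <- segment_thigh_surface(ph$volume, truth_mask(ph, "femur"))
  at <- estimate_ct_at(ph$volume, s$sphere)
  n <- mask_count(at$voi_at)
  expect_gt(n, 500)
  expect_lt(abs(at$ct_at + 100), 3 * 10 / sqrt(n) + 0.2)
})

test_that("a sphere placed in air fails with a placement hint", {
  ph <- small_phantom()
  air_sphere <- voxel_mask(mlsct:::sphere_mask(dim(ph$volume$data),
                                               c(3, 3, 3), 2),
                           ph$volume, "sphere")
  expect_error(estimate_ct_at(ph$volume, air_sphere), "misplaced")
})

test_that("the contrast scale is anchored at CT_AT and CT_H2O", {
  ctx <- calibration_context(ct_h2o = 0, ct_at = -100)
  v <- ct_volume(array(c(-100, 0, -50, 40, 700, -1000, 20, 10), c(2, 2, 2)),
                 check_range = FALSE)
  cm <- contrast_map(v, ctx)
  expect_equal(cm[1, 1, 1], 0)    # CT value of adipose tissue
  expect_equal(cm[2, 1, 1], 1)    # CT value of water
  expect_equal(cm[1, 2, 1], 0.5)  # midway, by linearity
  expect_gt(cm[1, 1, 2], 1)       # bone far above water
})

test_that("the contrast map is invariant under a global affine shift", {
  ph <- generate_thigh_phantom(phantom_spec(dim = c(48, 48, 8), n_legs = 1,
                                            leg_radius = 20, sat_thickness = 6,
                                            femur_radius = 4, pat_thickness = 1,
                                            water_insert_radius = 0,
                                            acetabulum_slice = 1))
  ctx1 <- calibration_context(0, -100)
  ctx2 <- calibration_context(25, -75)
  v2 <- ct_volume(ph$volume$data + 25, spacing = ph$volume$spacing,
                  check_range = FALSE)
  expect_equal(contrast_map(ph$volume, ctx1), contrast_map(v2, ctx2))
})


test_that("T_AT equals the trimmed-statistic oracle on random spectra", {
  set.seed(42)
  for (rep in 1:5) {
    hu <- rnorm(40000, mean = -100, sd = runif(1, 6, 14))
    dm <- c(40, 40, 25)
    vol <- ct_volume(array(hu, dm), check_range = FALSE)
    mask <- array(TRUE, dm)
    res <- compute_t_at(vol, mask)
    expect_equal(res$t_at, oracle_t_at(hu), tolerance = 1e-10)
  }
})

test_that("T_AT is insensitive to sub-30%-of-mode contamination", {
  set.seed(7)
  hu <- rnorm(50000, -100, 10)
  contaminated <- c(hu, rep(20, 500))   # 1% vessel voxels at +20 HU
  v1 <- ct_volume(array(hu, c(50, 50, 20)), check_range = FALSE)
  v2 <- ct_volume(array(contaminated, c(50, 101, 10)), check_range = FALSE)
  t1 <- compute_t_at(v1, array(TRUE, c(50, 50, 20)))$t_at
  t2 <- compute_t_at(v2, array(TRUE, c(50, 101, 10)))$t_at
  expect_lt(abs(t1 - t2), 0.5)
})

test_that("narrow spectra are rejected", {
  v <- flat_volume(c(5, 5, 5), -100)
  expect_error(compute_t_at(v, array(TRUE, c(5, 5, 5))), "10")
  expect_error(compute_t_at(v, array(FALSE, c(5, 5, 5))), "empty")
})

test_that("T_HDM is the 35 HU constant plus the water value", {
  expect_equal(compute_t_hdm(0), 35)
  expect_equal(compute_t_hdm(-4), 31)
  expect_equal(compute_t_hdm(5), 40)
  ctx <- calibration_context(ct_h2o = 2, ct_at = -95)
  expect_equal(ctx$t_hdm, 37)
  # shifting CT_H2O by delta shifts T_HDM by exactly delta
  d <- calibration_context(ct_h2o = 7, ct_at = -95)$t_hdm - ctx$t_hdm
  expect_equal(d, 5)
  expect_error(calibration_context(ct_h2o = -100, ct_at = -50), "CT_AT")
})
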