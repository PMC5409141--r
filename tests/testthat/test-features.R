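# Density, relative volume, granulometry, fractal dimension, sphericity.

test_that("density is the VOI mean minus the water value, exactly equivariant", {
  dm <- c(10, 10, 5)
  vol <- flat_volume(dm, 35)
  voi <- array(TRUE, dm)
  expect_equal(density_hu(vol, voi, 0), 35)
  # the water-calibration mechanism: +5 HU on CT_H2O shifts D by -5 exactly
  expect_equal(density_hu(vol, voi, 5), 30)
  expect_error(density_hu(vol, array(FALSE, dm), 0), "empty")
  # zero-mean noise moves D by at most a few standard errors
  set.seed(1)
  noisy <- add_gaussian_noise(vol, 10, seed = 3)
  expect_lt(abs(density_hu(noisy, voi, 0) - 35), 3 * 10 / sqrt(prod(dm)))
})

test_that("GMM density subtracts CT_H2O from the fitted component mean", {
  fit <- structure(list(at = c(h = 1, m = -100, s = 10),
                        mt = c(h = 1, m = 35, s = 12),
                        a = -30, b = 35, converged = TRUE),
                   class = "gmm_fit")
  expect_equal(gmm_density(fit, "mt", 0), 35)
  expect_equal(gmm_density(fit, "mt", -2), 37)
  expect_equal(gmm_density(fit, "at", 0), -100)
  fit$converged <- FALSE
  expect_error(gmm_density(fit, "mt", 0), "convergent")
})

test_that("relative volume is a voxel-count ratio with containment checks", {
  dm <- c(8, 8, 8)
  ref <- array(TRUE, dm)
  voi <- array(FALSE, dm); voi[1:4, , ] <- TRUE
  expect_equal(relative_volume(ref, ref), 1)
  expect_equal(relative_volume(voi, ref), 0.5)
  expect_error(relative_volume(voi, array(FALSE, dm)), "empty")
  out <- array(FALSE, dm); out[5:8, , ] <- TRUE
  expect_warning(rv <- relative_volume(out, voi), "contained")
  expect_equal(rv, 0)
})

test_that("granulometry: single-grain size, additivity, erosion monotone", {
  b10 <- digital_ball(5, n = 21)
  g10 <- granulometry_avg(b10, c(1, 1, 1))
  expect_lt(abs(g10 - 10), 1)
  # two grain sizes combine as the volume-weighted mean of their own sizes
  b6 <- digital_ball(3, n = 13)
  scene <- array(FALSE, c(48, 21, 21))
  scene[1:21, , ] <- b10
  scene[31:43, 5:17, 5:17] <- b6
  g_mix <- granulometry_avg(scene, c(1, 1, 1))
  g6 <- granulometry_avg(b6, c(1, 1, 1))
  v10 <- sum(b10); v6 <- sum(b6)
  oracle <- (g10 * v10 + g6 * v6) / (v10 + v6)
  expect_lt(abs(g_mix - oracle), 0.15)
  # near-equal-volume mixture of 6 and 12 mm grains averages to about 9
  b12 <- digital_ball(6, n = 21)
  k <- round(sum(b12) / sum(b6))
  scene2 <- array(FALSE, c(21 + k * 14, 21, 21))
  scene2[1:21, , ] <- b12
  for (t in seq_len(k))
    scene2[21 + (t - 1) * 14 + (1:13), 5:17, 5:17] <- b6
  g2 <- granulometry_avg(scene2, c(1, 1, 1))
  v12 <- sum(b12)
  oracle2 <- (12 * v12 + 6 * k * sum(b6)) / (v12 + k * sum(b6))
  expect_lt(abs(g2 - oracle2), 1)
  # eroding a structure reduces the average grain size
  er <- erode_ball(b10, 1)
  expect_lt(granulometry_avg(er, c(1, 1, 1)), g10)
})

test_that("fractal dimension: surface about 2, line about 1, sponge triadic", {
  cube <- digital_cuboid(c(80, 80, 80))
  expect_lt(abs(fractal_dimension(cube) - 2), 0.15)
  line <- array(FALSE, c(80, 20, 20)); line[5:68, 10, 10] <- TRUE
  expect_lt(abs(fractal_dimension(line, boundary = FALSE) - 1), 0.15)
  m3 <- menger_sponge(3)
  expect_lt(abs(fractal_dimension(m3, boundary = FALSE, eps = c(1, 3, 9)) -
                  log(20) / log(3)), 0.15)
  expect_error(fractal_dimension(digital_cuboid(c(2, 2, 2))), "scales")
})

test_that("sphericity: ball near 1, cube near its closed form, elongation lowers it", {
  expect_gt(sphericity(digital_ball(20), c(1, 1, 1)), 0.97)
  expect_lte(sphericity(digital_ball(20), c(1, 1, 1)), 1.005)
  cube <- digital_cuboid(c(40, 40, 40))
  expect_lt(abs(sphericity(cube, c(1, 1, 1)) - (pi / 6)^(1 / 3)), 0.03)
  slab <- digital_cuboid(c(8, 8, 64))
  expect_lt(sphericity(slab, c(1, 1, 1)), sphericity(digital_cuboid(c(16, 16, 16)),
                                                     c(1, 1, 1)))
  expect_error(sphericity(array(FALSE, c(4, 4, 4))), "voxels")
})

test_that("texture features are invariant to translation and 90-degree rotation", {
  set.seed(3)
  blob <- digital_ball(14, n = 70)
  blob[20:24, 20:24, 3:68] <- TRUE
  shifted <- array(FALSE, c(76, 76, 76))
  shifted[3 + 1:70, 2 + 1:70, 4 + 1:70] <- blob
  rotated <- aperm(blob, c(2, 3, 1))
  expect_equal(granulometry_avg(blob, c(1, 1, 1)),
               granulometry_avg(shifted, c(1, 1, 1)))
  expect_equal(granulometry_avg(blob, c(1, 1, 1)),
               granulometry_avg(rotated, c(1, 1, 1)))
  expect_equal(fractal_dimension(blob), fractal_dimension(shifted))
  expect_equal(fractal_dimension(blob), fractal_dimension(rotated))
})

test_that("feature extraction does not mutate its input masks", {
  b <- digital_ball(8, n = 25)
  b0 <- b
  invisible(granulometry_avg(b, c(1, 1, 1)))
  invisible(fractal_dimension(b, eps = c(1, 2, 4)))
  invisible(sphericity(b, c(1, 1, 1)))
  expect_identical(b, b0)
})

test_that("anisotropic spacing is honoured in mm-valued features", {
  # 20 mm ball sampled at 1x1x2 mm
  b <- digital_ball(10, n = 31, spacing = c(1, 1, 2))
  g <- granulometry_avg(b, c(1, 1, 2))
  expect_lt(abs(g - 20), 1.5)
  s <- sphericity(b, c(1, 1, 2))
  expect_gt(s, 0.93)
})
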