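# SAT/PAT/M/MT partition, mixture decomposition, concentration bins.

test_that("SAT excludes VOI_IF and the dermis-connected set", {
  b <- small_bundle()
  m <- b$masks
  expect_equal(sum(m$VOI_SAT$data & m$VOI_IF$data), 0)
  expect_equal(sum(m$VOI_SAT$data & m$dermis$data), 0)
  ph <- small_phantom()
  labs <- ph$truth$labels
  expect_equal(sum(m$VOI_SAT$data & labs == 1L), 0)  # no dermis voxels
  expect_error(segment_sat(m$VOI_IF$data, m$VOI_IF$data,
                           array(FALSE, dim(labs))), "empty")
})

test_that("PAT/M: fascia connectivity, strict threshold, volume conservation", {
  ph <- fine_phantom()
  b <- fine_bundle()
  m <- b$masks
  labs <- ph$truth$labels
  slab <- session_slab(ph, b$session)
  # EML grains in the muscle interior are not fascia-connected: they stay
  # in M, never in PAT (grains that touch the fascia-adjacent layer are
  # PAT by the connectivity definition and are excluded here)
  other <- array(!(labs %in% c(5L, 6L)), dim(labs))
  interior_eml <- labs == 5L & slab & edt(other) > 2
  expect_gt(sum(interior_eml), 0)
  expect_equal(sum(m$VOI_PAT$data & interior_eml), 0)
  expect_true(all(m$VOI_M$data[interior_eml]))
  # exact partition of VOI_IF
  expect_equal(sum(m$VOI_PAT$data) + sum(m$VOI_M$data) +
                 sum(m$femur_dil$data & m$VOI_IF$data),
               sum(m$VOI_IF$data))
  # a voxel exactly at T_AT is not PAT (strict <)
  dm <- c(20, 20, 6)
  vol <- flat_volume(dm, -70)
  voi_if <- array(FALSE, dm); voi_if[5:15, 5:15, ] <- TRUE
  fascia <- mask_boundary(voi_if)
  res <- segment_pat_and_m(vol, voi_if, fascia, t_at = -70,
                           femur_mask = array(FALSE, dm))
  expect_equal(sum(res$pat), 0)
  res2 <- segment_pat_and_m(vol, voi_if, fascia, t_at = -69.999,
                            femur_mask = array(FALSE, dm))
  expect_gt(sum(res2$pat), 0)
})

test_that("the two-Gaussian fit recovers known mixture parameters", {
  set.seed(5)
  n <- 1e6
  draws <- c(rnorm(0.6 * n, -105, 12), rnorm(0.4 * n, 35, 15))
  dm <- c(100, 100, 100)
  vol <- ct_volume(array(draws, dm), check_range = FALSE)
  star <- mlsct:::trimmed_sat_star(-160:-60,
                                   round(dnorm(-160:-60, -105, 12) * 1e5))
  ctx <- calibration_context(0, -105, t_at = -80)
  fit <- fit_gmm(vol, array(TRUE, dm), star, n_voi_at = 0.6 * n, ctx)
  expect_true(fit$converged)
  expect_lt(abs(fit$at[["m"]] + 105), 1)
  expect_lt(abs(fit$mt[["m"]] - 35), 1)
  expect_lt(abs(fit$at[["s"]] - 12) / 12, 0.05)
  expect_lt(abs(fit$mt[["s"]] - 15) / 15, 0.05)
  expect_true(fit$a > -105 && fit$a < 35)
})

test_that("the component intersection matches a 0.01-HU grid scan", {
  g <- function(x, h, m, s) h * exp(-(x - m)^2 / (2 * s^2))
  cases <- list(c(1, -105, 12, 0.7, 35, 15),
                c(2, -100, 10, 2, -20, 10),     # equal SD/height -> midpoint
                c(5, -90, 8, 0.3, 40, 20))
  for (p in cases) {
    a <- gmm_intersection(p[1], p[2], p[3], p[4], p[5], p[6])
    grid <- seq(p[2], p[5], by = 0.01)
    brute <- grid[which.min(abs(g(grid, p[1], p[2], p[3]) -
                                  g(grid, p[4], p[5], p[6])))]
    expect_lt(abs(a - brute), 0.011)
  }
  expect_equal(gmm_intersection(2, -100, 10, 2, -20, 10), -60)
})

test_that("MT growing equals thresholding when connectivity allows", {
  ph <- fine_phantom()
  b <- fine_bundle()
  expect_true(b$gmm_mls$converged)
  domain <- b$masks$VOI_IF$data & !b$masks$femur_dil$data
  thresh <- domain & ph$volume$data > b$gmm_mls$a
  # on the noiseless phantom every above-threshold voxel is 26-connected
  # to a seed, so growing must reduce to the plain threshold set
  expect_identical(b$masks$VOI_MT$data, thresh)
})

test_that("a lone supra-peak island surrounded by sub-a voxels is kept", {
  dm <- c(15, 15, 7)
  hu <- array(-100, dm)
  hu[8, 8, 4] <- 60
  vol <- ct_volume(hu, check_range = FALSE)
  voi_if <- array(TRUE, dm)
  fit <- structure(list(a = -30, b = 50, converged = TRUE,
                        at = c(h = 1, m = -100, s = 10),
                        mt = c(h = 1, m = 50, s = 10)), class = "gmm_fit")
  mt <- segment_mt(vol, voi_if, fit, array(FALSE, dm))
  expect_equal(which(mt), which(hu == 60))
  expect_warning(segment_mt(ct_volume(array(-100, dm), check_range = FALSE),
                            voi_if, fit, array(FALSE, dm)), "empty")
  fit$converged <- FALSE
  expect_error(segment_mt(vol, voi_if, fit, array(FALSE, dm)), "convergent")
})

test_that("concentration bins follow the printed edges and partition VOI_IF", {
  dm <- c(6, 6, 3)
  ctx <- calibration_context(0, -100, t_at = -80)   # T_HDM = 35
  hu <- array(0, dm)
  hu[1, 1, 1] <- 35       # 100% -> B6 (HDM)
  hu[2, 1, 1] <- -80      # 0%   -> B2 lower edge
  hu[3, 1, 1] <- (35 - 80) / 2  # midway -> 50% -> B4
  hu[4, 1, 1] <- -100     # below T_AT -> IMAT
  hu[5, 1, 1] <- 34.9     # 99.9% floors to 99 -> B5
  hu[6, 1, 1] <- -80.01   # just below 0 -> IMAT
  vol <- ct_volume(hu, check_range = FALSE)
  voi_if <- array(TRUE, dm)
  cb <- concentration_bins(vol, voi_if, ctx, array(FALSE, dm))
  expect_equal(cb$bin[1, 1, 1], 6L)
  expect_equal(cb$bin[2, 1, 1], 2L)
  expect_equal(cb$bin[3, 1, 1], 4L)
  expect_equal(cb$bin[4, 1, 1], 1L)
  expect_equal(cb$bin[5, 1, 1], 5L)
  expect_equal(cb$bin[6, 1, 1], 1L)
  expect_equal(sum(cb$bin > 0), prod(dm))
  # bins partition VOI_IF minus femur on the real bundle
  b <- small_bundle()
  expect_equal(sum(b$bins$bin > 0),
               sum(b$masks$VOI_IF$data & !b$masks$femur_dil$data))
})
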