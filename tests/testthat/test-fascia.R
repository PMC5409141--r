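# Grade formulas, aggregation, component logic, candidate rule, shielding.

test_that("grade parameters follow the printed linear formulas", {
  g1 <- grade_params(1)
  expect_equal(g1$c_min, 0.60)
  expect_equal(g1$alpha_min, 0.80)
  g3 <- grade_params(3)
  expect_equal(g3$c_min, 0.30)
  expect_equal(g3$alpha_min, 0.70)
  expect_error(grade_params(0), "range")
})

test_that("aggregation equals exhaustive 26-neighbour enumeration", {
  set.seed(11)
  dm <- c(9, 8, 7)
  cmap <- array(runif(prod(dm), 0, 1.5), dm)
  valid <- array(runif(prod(dm)) > 0.2, dm)
  c_min <- 0.6
  amap <- aggregation_map(cmap, c_min, valid)
  # brute force at 30 random voxels including corners
  pts <- rbind(c(1, 1, 1), c(9, 8, 7),
               cbind(sample(9, 28, TRUE), sample(8, 28, TRUE),
                     sample(7, 28, TRUE)))
  for (r in seq_len(nrow(pts))) {
    p <- pts[r, ]
    cnt <- 0
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      q <- p + c(di, dj, dk)
      if (any(q < 1) || any(q > dm)) next
      if (valid[q[1], q[2], q[3]] && cmap[q[1], q[2], q[3]] >= c_min)
        cnt <- cnt + 1
    }
    expect_equal(amap[p[1], p[2], p[3]], cnt / 26)
  }
  # ties pass: a neighbourhood exactly at the threshold counts fully
  cm2 <- array(c_min, c(3, 3, 3))
  expect_equal(aggregation_map(cm2, c_min)[2, 2, 2], 1)
})

test_that("potential muscle honours depth, femur connection and thresholds", {
  ph <- small_phantom()
  fem <- truth_mask(ph, "femur")
  surf <- segment_thigh_surface(ph$volume, fem)
  ctx0 <- calibration_context(0, -100)
  cmap <- contrast_map(ph$volume, ctx0)
  gp <- grade_params(1)
  amap <- aggregation_map(cmap, gp$c_min, surf$body$data)
  pm <- classify_potential_muscle(cmap, amap, gp, fem, surf$body)
  labs <- ph$truth$labels
  # dermis voxels (depth < 10) are always excluded
  expect_equal(sum(pm & labs == 1L), 0)
  # the kept set covers nearly all muscle deeper than 10 voxels; the first
  # and last slice fail the aggregation by the out-of-grid convention, so
  # the comparison stays inside the scanned extent
  depth <- edt(!surf$body$data)
  deep_muscle <- labs == 6L & depth >= 10
  deep_muscle[, , c(1, dim(depth)[3])] <- FALSE
  expect_gt(sum(pm & deep_muscle) / sum(deep_muscle), 0.95)
})

test_that("an isolated high-contrast blob away from the femur is dropped", {
  dm <- c(40, 40, 12)
  body <- array(TRUE, dm)
  cmap <- array(0, dm)
  cmap[16:25, 16:25, ] <- 1.2                    # femur-attached muscle block
  cmap[33:36, 33:36, ] <- 1.2                    # disconnected blob
  femur <- array(FALSE, dm); femur[19:22, 19:22, ] <- TRUE
  gp <- grade_params(1)
  amap <- aggregation_map(cmap, gp$c_min, body)
  cfg <- load_config(overrides = list(depth_min = 0))
  pm <- classify_potential_muscle(cmap, amap, gp, femur, body, cfg)
  expect_true(any(pm[16:25, 16:25, ]))
  expect_equal(sum(pm[33:36, 33:36, ]), 0)
})

test_that("monotonicity in G: the G=3 mask contains the G=1 mask", {
  ph <- small_phantom()
  fem <- truth_mask(ph, "femur")
  surf <- segment_thigh_surface(ph$volume, fem)
  ctx0 <- calibration_context(0, -100)
  cmap <- contrast_map(ph$volume, ctx0)
  masks <- lapply(c(1, 3), function(G) {
    gp <- grade_params(G)
    amap <- aggregation_map(cmap, gp$c_min, surf$body$data)
    classify_potential_muscle(cmap, amap, gp, fem, surf$body)
  })
  expect_equal(sum(masks[[1]] & !masks[[2]]), 0)
})

test_that("leg components are ranked by size and labelled by laterality", {
  dm <- c(60, 30, 6)
  m <- array(FALSE, dm)
  m[5:20, 10:20, ] <- TRUE      # right leg (low x), larger
  m[40:52, 10:20, ] <- TRUE     # left leg
  m[56:57, 25:26, ] <- TRUE     # small artifact blob
  femur <- array(FALSE, dm); femur[12:13, 14:15, ] <- TRUE
  femur[45:46, 14:15, ] <- TRUE
  legs <- select_leg_components(m, femur)
  expect_true(all(which(legs$rc, arr.ind = TRUE)[, 1] <= 20))
  expect_true(all(which(legs$lc, arr.ind = TRUE)[, 1] >= 40))
  expect_equal(sum(legs$rc) + sum(legs$lc), sum(m) - 2 * 2 * 6)
  single <- array(FALSE, dm); single[5:20, 10:20, ] <- TRUE
  expect_warning(res <- select_leg_components(single, femur), "one leg")
  expect_null(res$lc)
})

test_that("compactification closes holes and is extensive", {
  dm <- c(40, 40, 12)
  comp <- array(FALSE, dm)
  comp[8:32, 8:32, 2:11] <- TRUE
  comp[18:22, 18:22, 5:8] <- FALSE     # interior cavity
  ifa <- compactify(comp)
  expect_true(all(ifa[18:22, 18:22, 5:8]))
  expect_true(all(ifa[comp]))
  expect_error(compactify(array(FALSE, dm)), "empty")
})

test_that("the candidate predicate applies C>1, the g rule, and dermis exclusion", {
  # scene: IFA block; a fascia-like wall connected to FA by a thin bridge
  # (candidates must be grown from FA, a detached wall is never reached)
  dm <- c(30, 20, 10)
  hu <- array(-100, dm)
  ifa <- array(FALSE, dm); ifa[3:10, , ] <- TRUE
  hu[3:10, , ] <- 40
  hu[14, , ] <- 35                     # wall within reach: C = 1.35 -> accept
  hu[11:13, 1, ] <- 35                 # contact bridge from FA to the wall
  hu[20, , ] <- -60                    # C = 0.4 -> reject regardless
  vol <- ct_volume(hu, check_range = FALSE)
  ctx <- calibration_context(0, -100)
  cmap <- contrast_map(vol, ctx)
  dermis <- array(FALSE, dm)
  fc <- find_candidate_voxels(vol, cmap, ifa, dermis)
  expect_true(all(fc$candidates[14, , ]))
  expect_equal(sum(fc$candidates[20, , ]), 0)
  # a voxel satisfying f but with no connected path to FA stays out
  hu2 <- hu; hu2[11:13, 1, ] <- -100   # cut the bridge
  vol2 <- ct_volume(hu2, check_range = FALSE)
  fc2 <- find_candidate_voxels(vol2, contrast_map(vol2, ctx), ifa, dermis)
  expect_equal(sum(fc2$candidates[14, , ]), 0)
  # the g branch admits voxels with 0.5 <= C <= 1 above the local threshold
  hu3 <- hu; hu3[15:17, , ] <- -40     # C = 0.6 plate attached to the wall
  vol3 <- ct_volume(hu3, check_range = FALSE)
  fc3 <- find_candidate_voxels(vol3, contrast_map(vol3, ctx), ifa, dermis)
  expect_true(all(fc3$candidates[15:17, , ]))
  # an exact tie at mean26 - 2 SD26 passes: deep inside the uniform plate
  # all 26 neighbours are -40, so the threshold is exactly -40
  ns <- neighborhood_stats(vol3)
  expect_equal(ns$sd[16, 10, 5], 0)
  expect_equal(hu3[16, 10, 5], ns$mean[16, 10, 5] - 2 * ns$sd[16, 10, 5])
  expect_true(fc3$candidates[16, 10, 5])
  # marking the wall as dermis-connected removes it
  dermis2 <- array(FALSE, dm); dermis2[14, , ] <- TRUE; dermis2[11:13, 1, ] <- TRUE
  fc4 <- find_candidate_voxels(vol, cmap, ifa, dermis2)
  expect_equal(sum(fc4$candidates[14, , ]), 0)
})

test_that("ray shielding reflects the quorum rule exactly", {
  dm <- c(9, 9, 9)
  band <- array(TRUE, dm)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(offs != 0) > 0, ]
  build <- function(k) {
    cand <- array(FALSE, dm)
    for (r in seq_len(k)) cand[5 + offs[r, 1], 5 + offs[r, 2], 5 + offs[r, 3]] <- TRUE
    cand
  }
  ifa <- array(FALSE, dm)
  seed <- rbind(c(4, 4, 4))  # 0-based centre
  res26 <- ray_shielding(ifa, build(26), band, seed)
  expect_equal(res26$reflections[5, 5, 5], 26)
  expect_true(res26$shielded[5, 5, 5])
  res17 <- ray_shielding(ifa, build(17), band, seed)
  expect_equal(res17$reflections[5, 5, 5], 17)
  expect_true(res17$shielded[5, 5, 5])
  res16 <- ray_shielding(ifa, build(16), band, seed)
  expect_false(res16$shielded[5, 5, 5])
  expect_equal(res16$status[5, 5, 5], 1L)
  expect_error(ray_shielding(ifa, build(26), band, rbind(c(4, 4, 3))),
               "seed")
})

test_that("an open half-space is never shielded", {
  dm <- c(21, 21, 21)
  band <- array(TRUE, dm)
  cand <- array(FALSE, dm); cand[1:8, , ] <- TRUE
  res <- ray_shielding(array(FALSE, dm), cand, band, rbind(c(10, 10, 10)))
  expect_lte(res$reflections[11, 11, 11], 13)
  expect_false(res$shielded[11, 11, 11])
})

test_that("the shielded set grows with the candidate set", {
  dm <- c(31, 31, 9)
  band <- array(TRUE, dm)
  ifa <- array(FALSE, dm); ifa[14:18, 14:18, ] <- TRUE
  ring <- function(deg) {
    cand <- array(FALSE, dm)
    ci <- 16; cj <- 16
    for (i in 1:31) for (j in 1:31) {
      r <- sqrt((i - ci)^2 + (j - cj)^2)
      a <- atan2(j - cj, i - ci) * 180 / pi
      if (r >= 8 && r <= 10 && a > -deg / 2 && a < deg / 2) cand[i, j, ] <- TRUE
    }
    cand
  }
  seed <- rbind(c(21, 15, 4))
  resA <- ray_shielding(ifa, ring(200), band, seed)
  resB <- ray_shielding(ifa, ring(330), band, seed)
  expect_equal(sum(resA$shielded & !resB$shielded), 0)
  expect_gte(sum(resB$shielded), sum(resA$shielded))
})

test_that("finalize_if merges, fills, smooths, and honours rejections", {
  cfg <- load_config()
  dm <- c(40, 40, 10)
  ifa <- array(FALSE, dm); ifa[10:30, 10:20, ] <- TRUE
  cand <- array(FALSE, dm)
  cand[10:30, 26, ] <- TRUE            # detached wall forming a closed gap
  cand[10, 21:26, ] <- TRUE
  cand[30, 21:26, ] <- TRUE
  fin <- finalize_if(ifa, cand, shielded = NULL)
  # the enclosed gap between IFA and the wall is contour-filled
  expect_true(all(fin$voi_if[15:25, 22:24, 3:8]))
  # without candidates the result is the smoothed IFA
  fin0 <- finalize_if(ifa, array(FALSE, dm))
  sm <- close_ball(open_ball(ifa, cfg$smoothing_radius), cfg$smoothing_radius)
  expect_equal(fin0$voi_if, sm)
  # a porous thin cluster is removed by the opening
  porous <- array(FALSE, dm)
  porous[35:38, 30:39, seq(1, 9, by = 2)] <- TRUE   # 1-voxel-thick plates
  fin1 <- finalize_if(ifa, porous)
  expect_equal(sum(fin1$voi_if[35:38, 30:39, ]), 0)
  # operator rejection removes a whole conglomerate before merging
  fin2 <- finalize_if(ifa, cand, rejected = rbind(c(19, 25, 4)))
  expect_equal(fin2$voi_if, fin0$voi_if)
})
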