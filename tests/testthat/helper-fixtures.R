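# Shared fixtures: compact phantoms, ground-truth-derived operator
# sessions, digital test shapes.  Everything is generated in code at test
# time; heavier objects are memoized across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# one-leg phantom small enough for fast end-to-end runs
small_spec <- function(...) {
  phantom_spec(dim = c(160, 160, 36), spacing = c(1.2, 1.2, 1.0),
               n_legs = 1, leg_radius = 44, sat_thickness = 12,
               pat_thickness = 3, femur_radius = 8,
               water_insert_radius = 12, acetabulum_slice = 2, ...)
}

# one-leg phantom at clinical resolution (0.8 mm in plane) whose fascia
# sheet is a small volume fraction; used for compartment-volume recovery
fine_spec <- function(...) {
  phantom_spec(dim = c(208, 192, 30), spacing = c(0.8, 0.8, 1.0),
               n_legs = 1, leg_radius = 75, sat_thickness = 12,
               pat_thickness = 4, femur_radius = 11,
               water_insert_radius = 0, acetabulum_slice = 2, ...)
}

# one mid-rind PAT voxel every `stride` slices as shielding gap seeds
gt_gap_seeds <- function(ph, stride = 8) {
  labs <- ph$truth$labels
  dm <- dim(labs)
  seeds <- NULL
  pat <- phantom_label_code("pat")
  for (k in seq(3, dm[3] - 2, by = stride)) {
    w <- which(labs[, , k] == pat)
    if (!length(w)) next
    ij <- cbind((w - 1) %% dm[1], (w - 1) %/% dm[1])
    seeds <- rbind(seeds, c(ij[round(nrow(ij) / 2), ], k - 1))
  }
  seed_set(seeds, "gap", dm)
}

phantom_label_code <- function(name) {
  codes <- c(air = 0L, dermis = 1L, sat = 2L, fascia = 3L, pat = 4L,
             eml = 5L, muscle = 6L, femur = 7L, water = 8L, edema = 9L)
  codes[[name]]
}

# session replaying the phantom's ground-truth operator inputs; CT_H2O is
# measured once from the insert ROI (or 0 when the phantom has none) and
# carried in the session as the operator's calibration input
gt_session <- function(ph, grade = 2, stride = 8, n_slices = NULL) {
  ct_h2o <- if (ph$spec$water_insert_radius > 0)
    ct_h2o_from_roi(ph$volume, truth_water_roi(ph)) else 0
  nz <- dim(ph$volume$data)[3]
  prox <- ph$truth$acetabulum_slice
  if (is.null(n_slices)) n_slices <- nz - prox - 2L
  mls_session(grade = grade, seeds = gt_gap_seeds(ph, stride),
              proximal_slice = prox, n_slices = n_slices, ct_h2o = ct_h2o)
}

# slab mask matching a session's analysis slices
session_slab <- function(ph, session) {
  dm <- dim(ph$volume$data)
  slab <- array(FALSE, dm)
  k0 <- session$proximal_slice + 1L
  k1 <- min(dm[3], session$proximal_slice + session$n_slices)
  slab[, , k0:k1] <- TRUE
  slab
}

small_phantom <- function() cached("small_ph", generate_thigh_phantom(small_spec()))

# noiseless clinical-resolution phantom + its segmentation, built on demand
fine_phantom <- function() cached("fine_ph",
                                  generate_thigh_phantom(fine_spec(noise_sd = 0)))
fine_bundle <- function() cached("fine_bundle", {
  ph <- fine_phantom()
  suppressWarnings(run_segment(ph$volume, truth_mask(ph, "femur"),
                               gt_session(ph, stride = 6)))
})
small_bundle <- function() cached("small_bundle", {
  ph <- small_phantom()
  ses <- gt_session(ph)
  suppressWarnings(run_segment(ph$volume, truth_mask(ph, "femur"), ses))
})

# ---- digital shapes -------------------------------------------------------

digital_ball <- function(r, n = 2 * ceiling(r) + 9, spacing = c(1, 1, 1)) {
  ctr <- (n + 1) / 2
  dx <- (seq_len(n) - ctr) * spacing[1]
  dy <- (seq_len(n) - ctr) * spacing[2]
  dz <- (seq_len(n) - ctr) * spacing[3]
  array(outer(outer(dx^2, dy^2, `+`), dz^2, `+`) <= r^2, c(n, n, n))
}

digital_cuboid <- function(len, pad = 4) {
  dm <- len + 2 * pad
  a <- array(FALSE, dm)
  a[pad + seq_len(len[1]), pad + seq_len(len[2]), pad + seq_len(len[3])] <- TRUE
  a
}

menger_sponge <- function(n_it) {
  n <- 3^n_it
  idx <- 0:(n - 1)
  arr <- array(TRUE, c(n, n, n))
  for (t in seq_len(n_it)) {
    ki <- (idx %/% 3^(t - 1)) %% 3 == 1
    a <- outer(outer(ki * 1, ki * 1, `+`), ki * 1, `+`)
    arr <- arr & (a < 2)
  }
  arr
}

# uniform HU volume helper
flat_volume <- function(dm, hu, spacing = c(1, 1, 1)) {
  ct_volume(array(hu, dm), spacing = spacing, check_range = FALSE)
}

# independent trimmed-statistic oracle operating on raw HU draws
oracle_t_at <- function(hu, cut = 0.3, k = 2) {
  tb <- table(round(hu))
  centers <- as.integer(names(tb))
  counts <- as.integer(tb)
  # contiguous support
  full <- min(centers):max(centers)
  cnt <- integer(length(full))
  cnt[match(centers, full)] <- counts
  mode_i <- which.max(cnt)
  thr <- cut * cnt[mode_i]
  lo <- 1; while (lo < mode_i && cnt[lo] < thr) lo <- lo + 1
  hi <- length(cnt); while (hi > mode_i && cnt[hi] < thr) hi <- hi - 1
  cc <- full[lo:hi]; cn <- cnt[lo:hi]
  m <- mode_i - lo + 1
  off <- 0:(length(cc) - m)
  sc <- c(rev(cc[m] - off[-1]), cc[m] + off)
  sn <- c(rev(cn[m + off[-1]]), cn[m + off])
  mu <- sum(sc * sn) / sum(sn)
  sdv <- sqrt(sum(sn * (sc - mu)^2) / sum(sn))
  mu + k * sdv
}
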