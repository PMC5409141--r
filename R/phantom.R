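# Synthetic CT thigh phantom with full ground truth.
#
# Geometry: one or two elliptic-cylinder legs (small smooth per-slice
# jitter), each consisting of, from the outside in: dermis shell,
# subcutaneous adipose tissue (SAT), a thin fascia sheet, an intrafascial
# space with an optional perimuscular-AT (PAT) rind over an angular sector,
# muscle with optional diffuse lipid infiltration (washed-out appearance)
# and optional AT-valued EML grains (moth-eaten appearance), and a femur.
# A water-insert cylinder posterior to the legs emulates the in-scan
# calibration phantom.

phantom_labels <- c(air = 0L, dermis = 1L, sat = 2L, fascia = 3L, pat = 4L,
                    eml = 5L, muscle = 6L, femur = 7L, water = 8L,
                    edema = 9L)

#' Specification of a synthetic thigh phantom
#'
#' Defaults describe an elderly-cohort-like two-leg thigh section on a
#' 256x256x60 grid at (1.2, 1.2, 1.0) mm spacing with 10 HU image noise.
#'
#' @param dim grid shape in voxels (nx, ny, nz).
#' @param spacing mm per voxel.
#' @param n_legs 1 or 2.
#' @param leg_radius outer (dermis) ellipse semi-axis along x, mm.
#' @param leg_aspect ratio of the y to the x semi-axis.
#' @param sat_thickness SAT layer thickness, mm.
#' @param dermis_thickness dermis shell thickness, voxels (in-plane).
#' @param fascia_thickness fascia sheet thickness, voxels (in-plane).
#' @param pat_thickness PAT rind thickness, voxels (in-plane); the rind
#'   covers `pat_sector_deg` degrees of the fascia circumference so the
#'   fascia stays in direct muscle contact elsewhere.
#' @param pat_sector_deg angular extent of the PAT rind, degrees.
#' @param femur_radius femoral shaft radius, mm.
#' @param hu named list of mean HU per tissue (`air`, `dermis`, `sat`,
#'   `fascia`, `muscle`, `bone`, `water`, `edema`).
#' @param lipid_infiltration diffuse lipid fraction in \[0, 1\]; lowers the
#'   muscle mean towards the SAT mean (washed-out appearance).
#' @param eml_density EML grain count per 100 mL of muscle.
#' @param eml_diameter EML grain diameter, mm.
#' @param edema_count edema/vessel blobs per leg placed in the SAT.
#' @param edema_radius blob radius, mm.
#' @param jitter relative per-slice radius modulation amplitude.
#' @param water_insert_radius radius of the water calibration insert, mm
#'   (0 disables it).
#' @param noise_sd Gaussian noise SD in HU.
#' @param acetabulum_slice 0-based index of the ground-truth most proximal
#'   analysis slice.
#' @param seed RNG seed; the phantom is bit-reproducible for a fixed spec.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(256, 256, 60), spacing = c(1.2, 1.2, 1.0),
                         n_legs = 2, leg_radius = 52, leg_aspect = 0.92,
                         sat_thickness = 12, dermis_thickness = 2,
                         fascia_thickness = 1, pat_thickness = 4,
                         pat_sector_deg = 120, femur_radius = 11,
                         hu = list(air = -1000, dermis = 60, sat = -100,
                                   fascia = 10, muscle = 40, bone = 700,
                                   water = 0, edema = 30),
                         lipid_infiltration = 0, eml_density = 2,
                         eml_diameter = 4, edema_count = 2, edema_radius = 2,
                         jitter = 0.02, water_insert_radius = 15,
                         noise_sd = 10, acetabulum_slice = 4, seed = 1L) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(s) {
  if (length(s$dim) != 3L || any(s$dim < 8))
    stop("phantom grid must be 3D with at least 8 voxels per axis")
  if (any(s$spacing <= 0)) stop("voxel spacing must be positive")
  if (!s$n_legs %in% 1:2) stop("n_legs must be 1 or 2")
  if (s$noise_sd < 0) stop("noise SD must be >= 0")
  if (s$lipid_infiltration < 0 || s$lipid_infiltration > 1)
    stop("lipid_infiltration must lie in [0, 1]")
  dxy <- mean(s$spacing[1:2])
  dermis_mm <- s$dermis_thickness * dxy
  fascia_mm <- s$fascia_thickness * dxy
  r_fascia_out <- s$leg_radius - dermis_mm - s$sat_thickness
  r_interior <- r_fascia_out - fascia_mm
  r_muscle_min <- r_interior - s$pat_thickness * dxy
  if (r_fascia_out <= 0)
    stop("geometry violation: SAT layer does not fit inside the dermis shell")
  if (r_interior <= 0)
    stop("geometry violation: fascia does not fit inside the SAT layer")
  if (s$femur_radius >= r_muscle_min)
    stop("geometry violation: femur (radius ", s$femur_radius,
         " mm) does not fit inside the muscle compartment (radius ",
         round(r_muscle_min, 1), " mm)")
  half_x <- s$dim[1] * s$spacing[1] / 2
  half_y <- s$dim[2] * s$spacing[2] / 2
  span_x <- if (s$n_legs == 2) 2 * s$leg_radius - 1 else s$leg_radius
  if (span_x * (1 + s$jitter) >= half_x)
    stop("geometry violation: legs (half-span ", round(span_x, 1),
         " mm) do not fit inside the grid (half-width ",
         round(half_x, 1), " mm)")
  if (s$leg_radius * s$leg_aspect * (1 + s$jitter) +
      (s$water_insert_radius > 0) * (2 * s$water_insert_radius + 8) >= half_y)
    stop("geometry violation: leg plus water insert does not fit inside the grid height")
  if (s$acetabulum_slice < 0 || s$acetabulum_slice >= s$dim[3])
    stop("acetabulum slice outside the grid")
  invisible(s)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic CT thigh phantom
#'
#' Renders the tissue model of [phantom_spec()] into an HU volume with
#' additive Gaussian noise and returns it together with the ground truth
#' (exclusive label map covering the grid, true volumes in mm^3, the true
#' proximal analysis slice and the true noise SD).
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` ([ct_volume()]), `truth` (list:
#'   `labels`, `volumes_mm3`, `acetabulum_slice`, `noise_sd`, `hu`),
#'   and `spec`.
#' @export
generate_thigh_phantom <- function(spec = phantom_spec()) {
  validate_phantom_spec(spec)
  dm <- as.integer(spec$dim)
  sp <- spec$spacing
  dxy <- mean(sp[1:2])
  x <- (seq_len(dm[1]) - (dm[1] + 1) / 2) * sp[1]
  y <- (seq_len(dm[2]) - (dm[2] + 1) / 2) * sp[2]

  dermis_mm <- spec$dermis_thickness * dxy
  fascia_mm <- spec$fascia_thickness * dxy
  pat_mm <- spec$pat_thickness * dxy
  r_fascia_out <- spec$leg_radius - dermis_mm - spec$sat_thickness
  r_interior <- r_fascia_out - fascia_mm

  centers <- if (spec$n_legs == 2)
    list(c(-(spec$leg_radius - 1), 0), c(spec$leg_radius - 1, 0))
  else list(c(0, 0))

  labels <- array(phantom_labels[["air"]], dim = dm)

  out <- with_seed(spec$seed, {
    phases <- stats::runif(length(centers), 0, 2 * pi)
    sector_mid <- stats::runif(1, 0, 2 * pi)

    for (k in seq_len(dm[3])) {
      rho <- 1 + spec$jitter * sin(2 * pi * (k - 1) / dm[3] + phases)
      slice <- matrix(phantom_labels[["air"]], dm[1], dm[2])
      for (li in seq_along(centers)) {
        cc <- centers[[li]]
        dx <- x - cc[1]
        dy <- (y - cc[2]) / spec$leg_aspect
        u <- sqrt(outer(dx^2, dy^2, `+`)) / rho[li]
        theta <- atan2(matrix(rep(dy, each = dm[1]), dm[1]),
                       matrix(rep(dx, dm[2]), dm[1]))
        inside <- u <= spec$leg_radius
        slice[inside & u > spec$leg_radius - dermis_mm] <- phantom_labels[["dermis"]]
        slice[inside & u <= spec$leg_radius - dermis_mm & u > r_fascia_out] <-
          phantom_labels[["sat"]]
        slice[u <= r_fascia_out & u > r_interior] <- phantom_labels[["fascia"]]
        interior <- u <= r_interior
        slice[interior] <- phantom_labels[["muscle"]]
        if (spec$pat_thickness > 0 && spec$pat_sector_deg > 0) {
          dtheta <- abs(((theta - sector_mid + pi) %% (2 * pi)) - pi)
          in_sector <- dtheta <= pi * spec$pat_sector_deg / 360
          slice[interior & u > r_interior - pat_mm & in_sector] <-
            phantom_labels[["pat"]]
        }
        slice[u <= spec$femur_radius] <- phantom_labels[["femur"]]
      }
      labels[, , k] <- slice
    }

    # EML grains: AT-valued spheres fully inside muscle
    muscle_idx <- which(labels == phantom_labels[["muscle"]])
    muscle_ml <- length(muscle_idx) * prod(sp) / 1e5   # units of 100 mL
    n_grains <- round(spec$eml_density * muscle_ml)
    if (n_grains > 0 && length(muscle_idx)) {
      pick <- sample(muscle_idx, n_grains)
      labels <- stamp_spheres(labels, pick, spec$eml_diameter / 2, sp,
                              onto = phantom_labels[["muscle"]],
                              value = phantom_labels[["eml"]])
    }
    # edema / vessel blobs in the SAT
    sat_idx <- which(labels == phantom_labels[["sat"]])
    n_blobs <- spec$edema_count * length(centers)
    if (n_blobs > 0 && length(sat_idx)) {
      pick <- sample(sat_idx, n_blobs)
      labels <- stamp_spheres(labels, pick, spec$edema_radius, sp,
                              onto = phantom_labels[["sat"]],
                              value = phantom_labels[["edema"]])
    }
    # water calibration insert posterior to the legs
    if (spec$water_insert_radius > 0) {
      wy <- max(y[abs(y) <= spec$leg_radius * spec$leg_aspect]) +
        8 + spec$water_insert_radius
      wu <- sqrt(outer(x^2, (y - wy)^2, `+`))
      wmask <- wu <= spec$water_insert_radius
      for (k in seq_len(dm[3])) {
        slice <- labels[, , k]
        slice[wmask & slice == phantom_labels[["air"]]] <-
          phantom_labels[["water"]]
        labels[, , k] <- slice
      }
    }

    muscle_mean <- (1 - spec$lipid_infiltration) * spec$hu$muscle +
      spec$lipid_infiltration * spec$hu$sat
    means <- c(spec$hu$air, spec$hu$dermis, spec$hu$sat, spec$hu$fascia,
               spec$hu$sat, spec$hu$sat, muscle_mean, spec$hu$bone,
               spec$hu$water, spec$hu$edema)
    vol <- array(means[labels + 1L], dim = dm)
    if (spec$noise_sd > 0)
      vol <- vol + array(rnorm(length(vol), 0, spec$noise_sd), dim = dm)
    list(vol = vol, labels = labels, muscle_mean = muscle_mean)
  })

  counts <- tabulate(out$labels + 1L, nbins = length(phantom_labels))
  volumes <- counts * prod(sp)
  names(volumes) <- names(phantom_labels)
  volume <- ct_volume(out$vol, spacing = sp, check_range = FALSE)
  truth <- list(labels = out$labels, volumes_mm3 = volumes,
                acetabulum_slice = spec$acetabulum_slice,
                noise_sd = spec$noise_sd,
                hu = modifyList(spec$hu, list(muscle = out$muscle_mean)))
  list(volume = volume, truth = truth, spec = spec)
}

# paint spheres of radius r_mm around the given linear voxel centres,
# only over voxels currently labelled `onto`
stamp_spheres <- function(labels, centers_idx, r_mm, sp, onto, value) {
  dm <- dim(labels)
  rv <- ceiling(r_mm / sp)
  off <- expand.grid(di = -rv[1]:rv[1], dj = -rv[2]:rv[2], dk = -rv[3]:rv[3])
  keep <- (off$di * sp[1])^2 + (off$dj * sp[2])^2 + (off$dk * sp[3])^2 <= r_mm^2
  off <- off[keep, , drop = FALSE]
  for (cidx in centers_idx) {
    c0 <- cidx - 1L
    ci <- c0 %% dm[1]
    cj <- (c0 %/% dm[1]) %% dm[2]
    ck <- c0 %/% (dm[1] * dm[2])
    ii <- ci + off$di; jj <- cj + off$dj; kk <- ck + off$dk
    ok <- ii >= 0 & ii < dm[1] & jj >= 0 & jj < dm[2] & kk >= 0 & kk < dm[3]
    lin <- 1L + ii[ok] + dm[1] * (jj[ok] + dm[2] * kk[ok])
    lin <- lin[labels[lin] == onto]
    labels[lin] <- value
  }
  labels
}

#' Ground-truth masks from a phantom
#'
#' Convenience accessors: `truth_mask` returns the mask of one or more
#' labels, `truth_intrafascia` the ground-truth intrafascial VOI (fascia
#' sheet and everything it encloses), `truth_water_roi` an eroded water
#' insert ROI for water calibration.
#'
#' @param phantom result of [generate_thigh_phantom()].
#' @param labels character vector of label names (see the `phantom_labels`
#'   names: air, dermis, sat, fascia, pat, eml, muscle, femur, water, edema).
#' @return a [voxel_mask()].
#' @export
truth_mask <- function(phantom, labels) {
  codes <- phantom_labels[labels]
  if (anyNA(codes)) stop("unknown phantom label(s): ",
                         paste(labels[is.na(codes)], collapse = ", "))
  voxel_mask(array(phantom$truth$labels %in% codes,
                   dim = dim(phantom$truth$labels)),
             phantom$volume, paste(labels, collapse = "+"))
}

#' @rdname truth_mask
#' @export
truth_intrafascia <- function(phantom) {
  m <- truth_mask(phantom, c("fascia", "pat", "eml", "muscle", "femur"))
  m$name <- "VOI_IF_truth"
  m
}

#' @rdname truth_mask
#' @export
truth_water_roi <- function(phantom) {
  w <- truth_mask(phantom, "water")
  roi <- erode_ball(w$data, 2)
  voxel_mask(roi, phantom$volume, "water_roi")
}

#' Add Gaussian noise to a CT volume
#'
#' Independent zero-mean Gaussian noise per voxel; deterministic for a
#' fixed seed.
#'
#' @param vol a [ct_volume()].
#' @param sd_add noise SD to add, HU (>= 0).
#' @param seed RNG seed.
#' @return a [ct_volume()].
#' @export
add_gaussian_noise <- function(vol, sd_add, seed = 1L) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!is.finite(sd_add) || sd_add < 0) stop("sd_add must be >= 0")
  if (sd_add == 0) return(vol)
  dat <- with_seed(seed, vol$data +
                     array(rnorm(length(vol$data), 0, sd_add),
                           dim = dim(vol$data)))
  ct_volume(dat, spacing = vol$spacing, origin = vol$origin,
            check_range = FALSE)
}

#' Additional noise SD for a simulated exposure change
#'
#' Because independent Gaussian noise adds in quadrature, reaching a total
#' noise of `k * sd_current` requires adding noise of SD
#' `sd_current * sqrt(k^2 - 1)`.  In `"multiplier"` mode `param` is the
#' target factor k (>= 1).  In `"mAs"` mode the quantum-noise model
#' SD proportional to 1/sqrt(mAs) is used: `param = c(mAs_old, mAs_new)`
#' with `mAs_new <= mAs_old`, giving
#' `sd_add = sd_current * sqrt(mAs_old / mAs_new - 1)`.
#'
#' @param sd_current current noise SD, HU.
#' @param mode `"multiplier"` or `"mAs"`.
#' @param param target factor, or `c(mAs_old, mAs_new)`.
#' @return the SD (HU) of the noise to add.
#' @export
noise_sd_for_exposure_change <- function(sd_current,
                                         mode = c("multiplier", "mAs"),
                                         param) {
  mode <- match.arg(mode)
  if (sd_current < 0) stop("sd_current must be >= 0")
  if (mode == "multiplier") {
    k <- param[1]
    if (!is.finite(k) || k < 1)
      stop("noise factor k must be >= 1 (noise cannot be removed)")
    sd_current * sqrt(k^2 - 1)
  } else {
    if (length(param) != 2L) stop("mAs mode needs param = c(mAs_old, mAs_new)")
    mas_old <- param[1]; mas_new <- param[2]
    if (mas_old <= 0 || mas_new <= 0) stop("mAs values must be positive")
    if (mas_new > mas_old)
      stop("mAs_new must not exceed mAs_old (noise cannot be removed)")
    sd_current * sqrt(mas_old / mas_new - 1)
  }
}

#' Write a phantom to disk
#'
#' Volume and label map as NIfTI or MetaImage, ground-truth summary and
#' spec as JSON.
#'
#' @param phantom result of [generate_thigh_phantom()].
#' @param dir output directory (created if missing).
#' @param format `"nii.gz"` or `"mha"`.
#' @return the directory, invisibly.
#' @export
write_phantom <- function(phantom, dir, format = c("nii.gz", "mha")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume(phantom$volume, file.path(dir, paste0("volume.", format)))
  # label map is written as an integer image through the volume writer
  labvol <- ct_volume(array(as.numeric(phantom$truth$labels),
                            dim = dim(phantom$truth$labels)),
                      spacing = phantom$volume$spacing, check_range = FALSE)
  write_volume(labvol, file.path(dir, paste0("labels.", format)))
  truth <- phantom$truth[c("volumes_mm3", "acetabulum_slice", "noise_sd", "hu")]
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  spec <- unclass(phantom$spec)
  jsonlite::write_json(spec, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
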