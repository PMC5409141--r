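# Anatomic analysis VOI: thigh surface segmentation and the upper-shaft
# slab VOI_US scaled by femoral landmarks.

#' Segment the thigh surface
#'
#' A small spherical ROI is placed straddling the skin (at the first
#' air-to-tissue crossing along a ray cast from the lateral image border
#' towards the femur centroid, or the volume centre when no femur mask is
#' given).  The surface threshold is the 70% point between the lowest and
#' highest HU inside the sphere; the body is the largest 26-connected
#' component above that threshold, with 3D cavities filled.
#'
#' @param vol a [ct_volume()].
#' @param femur_mask optional [voxel_mask()] used to aim the placement ray.
#' @param sphere_center optional 0-based (i, j, k) to place the sphere
#'   manually.
#' @param config an `mls_config` list.
#' @return list with `body` and `sphere` ([voxel_mask()]s) and the
#'   threshold `t_surf` (HU).
#' @export
segment_thigh_surface <- function(vol, femur_mask = NULL,
                                  sphere_center = NULL,
                                  config = load_config()) {
  stopifnot(inherits(vol, "ct_volume"))
  dm <- dim(vol$data)
  if (is.null(sphere_center)) {
    target <- if (!is.null(femur_mask)) {
      w <- which(mask_array(femur_mask))
      if (!length(w)) stop("femur mask is empty")
      c0 <- w - 1L
      round(c(mean(c0 %% dm[1]), mean((c0 %/% dm[1]) %% dm[2]),
              mean(c0 %/% (dm[1] * dm[2]))))
    } else round((dm - 1) / 2)
    j <- target[2] + 1L
    k <- target[3] + 1L
    line <- vol$data[, j, k]
    air_thr <- -400
    crossing <- which(line[-1] > air_thr & line[-length(line)] <= air_thr)
    if (!length(crossing))
      stop("no air-to-tissue crossing found along the placement ray; ",
           "place the surface sphere manually via `sphere_center`")
    sphere_center <- c(crossing[1], j - 1L, k - 1L)
  }
  r <- config$surface_sphere_radius
  sphere <- sphere_mask(dm, sphere_center, r)
  hu <- vol$data[sphere]
  t_surf <- min(hu) + config$surface_threshold_frac * (max(hu) - min(hu))
  body <- largest_components(vol$data >= t_surf, 1)
  if (!any(body)) stop("no body voxels above the surface threshold")
  body <- fill_cavities_3d(body)
  list(body = voxel_mask(body, vol, "body"),
       sphere = voxel_mask(sphere, vol, "surface_sphere"),
       t_surf = t_surf)
}

sphere_mask <- function(dm, center0, radius_vox) {
  di <- seq_len(dm[1]) - 1 - center0[1]
  dj <- seq_len(dm[2]) - 1 - center0[2]
  dk <- seq_len(dm[3]) - 1 - center0[3]
  d2 <- outer(outer(di^2, dj^2, `+`), dk^2, `+`)
  array(d2 <= radius_vox^2, dim = dm)
}

#' Compute the anatomic frame from the femur
#'
#' Plane A passes through the femur centre of mass in the
#' lesser-trochanter mid-height slice, perpendicular to the femoral shaft
#' axis (the principal axis of the femur mask).  P2 is the femoral-head
#' voxel at maximal distance from A on the head side; d is the projection
#' of the A-point-to-P2 vector onto the scanner z axis, and the analysis
#' slab contains n = floor(0.5 d / s) slices (minimum 1) for slice
#' thickness s.
#'
#' @param femur_mask a [voxel_mask()] of the femur.
#' @param trochanter_slice 0-based slice index of the lesser-trochanter
#'   mid-height.
#' @param spacing voxel spacing in mm (taken from the mask).
#' @return list of class `anatomic_frame`: `a_point` (mm), `axis` (unit),
#'   `p2` (0-based voxel), `d_mm`, `n_slices`.
#' @export
compute_anatomic_frame <- function(femur_mask, trochanter_slice,
                                   spacing = femur_mask$spacing) {
  m <- mask_array(femur_mask)
  dm <- dim(m)
  w <- which(m)
  if (length(w) < 100)
    stop("degenerate femur mask (fewer than 100 voxels)")
  c0 <- w - 1L
  vox <- cbind(c0 %% dm[1], (c0 %/% dm[1]) %% dm[2], c0 %/% (dm[1] * dm[2]))
  mm <- sweep(vox, 2, spacing, `*`)
  ctr <- colMeans(mm)
  pc <- eigen(stats::cov(mm), symmetric = TRUE)
  axis <- pc$vectors[, 1]
  axis <- axis / sqrt(sum(axis^2))
  in_slice <- vox[, 3] == trochanter_slice
  if (!any(in_slice))
    stop("femur mask is empty in the trochanter slice ", trochanter_slice)
  a_point <- colMeans(mm[in_slice, , drop = FALSE])
  # the head is proximal: under the fixed axial convention (slice index
  # grows distally) the head side is the decreasing-z direction
  if (abs(axis[3]) < 1e-6)
    stop("femoral shaft axis is perpendicular to the scanner z axis")
  if (axis[3] > 0) axis <- -axis
  s_dist <- as.numeric((mm - matrix(a_point, nrow(mm), 3, byrow = TRUE)) %*% axis)
  i2 <- which.max(s_dist)
  if (s_dist[i2] <= 0)
    stop("could not identify a femoral-head apex on the head side of plane A")
  p2 <- vox[i2, ]
  d_mm <- abs(mm[i2, 3] - a_point[3])
  if (d_mm <= 0) stop("degenerate anatomic distance d = 0")
  n <- max(1L, floor(0.5 * d_mm / spacing[3]))
  structure(list(a_point = a_point, axis = axis, p2 = p2,
                 d_mm = d_mm, n_slices = as.integer(n)),
            class = "anatomic_frame")
}

#' Define the analysis slab VOI_US
#'
#' The body mask restricted to `n_slices` contiguous slices extending
#' distally (towards increasing slice index) from the most proximal slice,
#' which is the distal end of the acetabulum.
#'
#' @param body_mask a [voxel_mask()] from [segment_thigh_surface()].
#' @param proximal_slice 0-based index of the most proximal slice.
#' @param n_slices slab slice count (e.g. from [compute_anatomic_frame()]).
#' @return a [voxel_mask()] named `VOI_US`.
#' @export
define_voi_us <- function(body_mask, proximal_slice, n_slices) {
  m <- mask_array(body_mask)
  dm <- dim(m)
  if (n_slices < 1) stop("n_slices must be >= 1")
  if (proximal_slice < 0 || proximal_slice >= dm[3])
    stop("proximal slice outside the grid")
  last <- proximal_slice + n_slices - 1L
  if (last >= dm[3]) {
    warning("analysis slab exceeds the grid and was clipped to ",
            dm[3] - proximal_slice, " slices")
    last <- dm[3] - 1L
  }
  slab <- array(FALSE, dim = dm)
  slab[, , (proximal_slice + 1L):(last + 1L)] <- TRUE
  voxel_mask(m & slab, body_mask, "VOI_US")
}
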