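# 3D binary morphology built on an exact (anisotropic) Euclidean distance
# transform, plus connected-component utilities.  Structuring elements are
# metric balls: a radius in voxels with unit weights, a radius in mm with
# the voxel spacing as weights, or an ellipsoid via per-axis semi-axes
# (weights 1/semi-axis, radius 1).

#' Squared / plain Euclidean distance transform
#'
#' Distance from every voxel to the nearest `TRUE` voxel of `mask`,
#' computed exactly (Felzenszwalb-Huttenlocher) under per-axis sample
#' weights.
#'
#' @param mask logical 3D array or `voxel_mask`.
#' @param weights length-3 positive weights (e.g. voxel spacing in mm, or
#'   `c(1,1,1)` for voxel units).
#' @return numeric array of (squared) distances; `Inf`-like large values
#'   (1e30) if the mask is empty.
#' @export
edt_sq <- function(mask, weights = c(1, 1, 1)) {
  m <- mask_array(mask)
  array(cpp_edt_sq(m, dim(m), as.numeric(weights)), dim = dim(m))
}

#' @rdname edt_sq
#' @export
edt <- function(mask, weights = c(1, 1, 1)) sqrt(edt_sq(mask, weights))

ball_tol <- 1e-7

#' Binary dilation / erosion / opening / closing by a metric ball
#'
#' @param mask logical 3D array or `voxel_mask`.
#' @param radius ball radius, in the units of `weights`.
#' @param weights per-axis metric weights; `c(1,1,1)` gives a ball in voxel
#'   units, the voxel spacing gives a ball in mm, and `1/semiaxes` with
#'   `radius = 1` gives an ellipsoid with the given semi-axes in voxels.
#' @return logical array.
#' @export
dilate_ball <- function(mask, radius, weights = c(1, 1, 1)) {
  if (radius < 0) stop("radius must be >= 0")
  edt_sq(mask, weights) <= radius^2 + ball_tol
}

#' @rdname dilate_ball
#' @export
erode_ball <- function(mask, radius, weights = c(1, 1, 1)) {
  m <- mask_array(mask)
  !dilate_ball(!m, radius, weights)
}

#' @rdname dilate_ball
#' @export
open_ball <- function(mask, radius, weights = c(1, 1, 1)) {
  if (radius == 0) return(mask_array(mask))
  dilate_ball(erode_ball(mask, radius, weights), radius, weights)
}

#' @rdname dilate_ball
#' @export
close_ball <- function(mask, radius, weights = c(1, 1, 1)) {
  if (radius == 0) return(mask_array(mask))
  erode_ball(dilate_ball(mask, radius, weights), radius, weights)
}

#' Morphological closing with an ellipsoidal structuring element
#'
#' @param mask logical 3D array or `voxel_mask`.
#' @param semiaxes length-3 semi-axes in voxels.
#' @return logical array.
#' @export
close_ellipsoid <- function(mask, semiaxes) {
  close_ball(mask, 1, weights = 1 / as.numeric(semiaxes))
}

#' 26-connected component labelling
#'
#' @param mask logical 3D array or `voxel_mask`.
#' @return integer array of labels (0 = background).
#' @export
label_components <- function(mask) {
  m <- mask_array(mask)
  array(cpp_label26(m, dim(m)), dim = dim(m))
}

#' Keep the n largest 26-connected components
#'
#' @param mask logical 3D array or `voxel_mask`.
#' @param n how many components to keep.
#' @return logical array (`n = 1`), or a list of logical arrays ordered by
#'   decreasing size (`n > 1`).
#' @export
largest_components <- function(mask, n = 1) {
  lab <- label_components(mask)
  if (max(lab) == 0L) {
    empty <- array(FALSE, dim = dim(lab))
    return(if (n == 1) empty else list())
  }
  sizes <- tabulate(lab)
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(n, length(sizes)))]
  if (n == 1) return(array(lab == keep[1], dim = dim(lab)))
  lapply(keep, function(l) array(lab == l, dim = dim(lab)))
}

#' 26-connected volume growing
#'
#' Breadth-first growth from seed voxels through an acceptance mask.
#' Seeds are always part of the result.
#'
#' @param accept logical array: voxels eligible to join.
#' @param seeds either a logical array of seed voxels or an integer matrix
#'   of 0-based (i, j, k) coordinates.
#' @return logical array.
#' @export
region_grow <- function(accept, seeds) {
  acc <- mask_array(accept)
  dm <- dim(acc)
  if (is.matrix(seeds)) {
    idx0 <- as.integer(linear_index(seeds, dm) - 1L)
  } else {
    idx0 <- which(mask_array(seeds)) - 1L
  }
  array(cpp_region_grow26(acc, as.integer(idx0), dm), dim = dm)
}

#' Cavity filling
#'
#' `fill_cavities_3d` fills background regions not 6-connected to the
#' volume border; `fill_cavities_slicewise` fills per-slice (xy) holes not
#' 4-connected to the slice border.
#'
#' @param mask logical 3D array or `voxel_mask`.
#' @return logical array.
#' @export
fill_cavities_3d <- function(mask) {
  m <- mask_array(mask)
  array(cpp_fill_3d(m, dim(m)), dim = dim(m))
}

#' @rdname fill_cavities_3d
#' @export
fill_cavities_slicewise <- function(mask) {
  m <- mask_array(mask)
  array(cpp_fill_slices(m, dim(m)), dim = dim(m))
}

#' Boundary voxels of a mask
#'
#' Mask voxels with at least one 6-neighbour outside the mask (or outside
#' the grid).  With `z_edge = "inside"` the volume is treated as if it
#' continued beyond the first and last slice (replicated), so the axial
#' truncation faces of a clipped scan do not count as surface; with
#' `z_edge = "ignore"` the z direction never creates boundary at all and
#' only the lateral (in-plane) surface is returned.
#'
#' @param mask logical 3D array or `voxel_mask`.
#' @param z_edge `"outside"` (default), `"inside"` or `"ignore"`.
#' @return logical array.
#' @export
mask_boundary <- function(mask, z_edge = c("outside", "inside", "ignore")) {
  z_edge <- match.arg(z_edge)
  m <- mask_array(mask)
  dm <- dim(m)
  shifted_all_inside <- array(TRUE, dim = dm)
  shift_one <- function(m, axis, by) {
    if (axis == 3L && z_edge == "ignore") return(m)
    out <- if (axis == 3L && z_edge == "inside") m
    else array(FALSE, dim = dim(m))
    idx_src <- lapply(dim(m), seq_len)
    idx_dst <- idx_src
    n <- dim(m)[axis]
    if (by == 1) {
      idx_dst[[axis]] <- 2:n; idx_src[[axis]] <- 1:(n - 1)
    } else {
      idx_dst[[axis]] <- 1:(n - 1); idx_src[[axis]] <- 2:n
    }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (axis in 1:3) for (by in c(1, -1))
    shifted_all_inside <- shifted_all_inside & shift_one(m, axis, by)
  m & !shifted_all_inside
}

#' Neighbourhood mean and standard deviation
#'
#' Mean and sample SD of the 26-neighbour HU values of every voxel
#' (neighbours outside the grid are absent from the statistic).
#'
#' @param vol a [ct_volume()] or numeric 3D array.
#' @return list with numeric arrays `mean` and `sd`.
#' @export
neighborhood_stats <- function(vol) {
  x <- if (inherits(vol, "ct_volume")) vol$data else vol
  res <- cpp_neighbor_mean_sd(x, dim(x))
  list(mean = array(res$mean, dim = dim(x)),
       sd = array(res$sd, dim = dim(x)))
}
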