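# Density, volume and 3D texture features of the muscle-lipid system.

#' Segmentation-based density
#'
#' Mean HU over a VOI after subtraction of the water value CT_H2O.
#'
#' @param vol a [ct_volume()].
#' @param voi a [voxel_mask()] or logical array.
#' @param ctx an [calibration_context()] (or a number taken as CT_H2O).
#' @return density D in HU.
#' @export
density_hu <- function(vol, voi, ctx) {
  m <- mask_array(voi)
  if (!any(m)) stop("cannot compute the density of an empty VOI")
  ct_h2o <- if (inherits(ctx, "mls_calibration")) ctx$ct_h2o else as.numeric(ctx)
  mean(vol$data[m]) - ct_h2o
}

#' GMM-based density
#'
#' Mean of a fitted mixture component after subtraction of CT_H2O;
#' computed for fits on VOI_IF and on VOI_MLS separately (D_IF^GMM,
#' D_MLS^GMM).
#'
#' @param fit a convergent [fit_gmm()] result.
#' @param component `"mt"` (muscle tissue) or `"at"` (adipose).
#' @param ctx an [calibration_context()] (or a number taken as CT_H2O).
#' @return density in HU.
#' @export
gmm_density <- function(fit, component = c("mt", "at"), ctx) {
  component <- match.arg(component)
  if (!inherits(fit, "gmm_fit") || !fit$converged)
    stop("GMM density requires a convergent fit")
  ct_h2o <- if (inherits(ctx, "mls_calibration")) ctx$ct_h2o else as.numeric(ctx)
  fit[[component]][["m"]] - ct_h2o
}

#' Relative volume
#'
#' Voxel-count ratio of a VOI to a reference VOI (equal spacing assumed).
#' A VOI that is not contained in the reference triggers a warning.
#'
#' @param voi,reference masks on one grid.
#' @return rV in \[0, 1\].
#' @export
relative_volume <- function(voi, reference) {
  v <- mask_array(voi); r <- mask_array(reference)
  check_same_grid(v, r)
  if (!any(r)) stop("empty reference VOI")
  if (any(v & !r)) warning("VOI is not contained in the reference VOI")
  sum(v & r) / sum(r)
}

#' Average grain size by granulometry
#'
#' Pattern spectrum from morphological openings with metric balls of
#' increasing radius: the volume fraction removed between successive
#' openings is attributed to the diameter of the last ball under which it
#' survived, and G_avg is the volume-weighted mean of those diameters
#' (in mm via the voxel spacing).
#'
#' @param voi a [voxel_mask()], or logical array (then `spacing` is used).
#' @param spacing voxel spacing in mm.
#' @param step radius increment in mm (default: the smallest spacing).
#' @return G_avg in mm.
#' @export
granulometry_avg <- function(voi, spacing = NULL, step = NULL) {
  m <- mask_array(voi)
  if (!any(m)) stop("cannot compute granulometry of an empty mask")
  if (is.null(spacing))
    spacing <- if (inherits(voi, "voxel_mask")) voi$spacing else c(1, 1, 1)
  if (is.null(step)) step <- min(spacing)
  total <- sum(m)
  prev <- total
  radii <- numeric(0)
  removed <- numeric(0)
  r <- step
  repeat {
    op <- sum(open_ball(m, r, weights = spacing))
    radii <- c(radii, r)
    removed <- c(removed, prev - op)
    prev <- op
    if (op == 0) break
    r <- r + step
  }
  # mass removed by the opening at radius r survived radius r - step:
  # attribute it to the grain diameter 2 (r - step) + one voxel step
  diam <- 2 * (radii - step) + step
  sum(diam * removed) / total
}

#' Box-counting fractal dimension
#'
#' 3D box counting on the boundary voxels of the mask: occupied box counts
#' N(eps) over dyadic box sizes eps = 1, 2, 4, ... up to one eighth of
#' the largest extent of the counted set (coarser boxes saturate the count
#' and bias the slope); FD is the least-squares slope of log N against
#' log(1/eps).  With `boundary = FALSE` the solid set is counted instead.
#'
#' @param voi mask.
#' @param boundary count the boundary voxels (texture-roughness reading)
#'   or the solid set.
#' @param eps optional integer vector of box sizes overriding the dyadic
#'   default (at least 3 scales), e.g. powers of 3 for triadic
#'   constructions.
#' @return FD (for a smooth closed surface about 2, for a line about 1).
#' @export
fractal_dimension <- function(voi, boundary = TRUE, eps = NULL) {
  m <- mask_array(voi)
  if (!any(m)) stop("cannot compute the fractal dimension of an empty mask")
  set <- if (boundary) mask_boundary(m) else m
  if (!any(set)) set <- m
  w <- which(set) - 1L
  dm <- dim(m)
  vox <- cbind(w %% dm[1], (w %/% dm[1]) %% dm[2], w %/% (dm[1] * dm[2]))
  vox <- sweep(vox, 2, apply(vox, 2, min))   # translation-invariant boxes
  extent <- apply(vox, 2, function(v) diff(range(v)) + 1)
  if (is.null(eps)) {
    emax <- max(1, floor(max(extent) / 8))
    eps <- 2^(0:floor(log2(emax)))
  }
  if (length(eps) < 3)
    stop("mask too small for box counting at >= 3 scales")
  counts <- vapply(eps, function(e) {
    nrow(unique(floor(vox / e)))
  }, numeric(1))
  unname(coef(lm(log(counts) ~ log(1 / eps)))[2])
}

#' Sphericity
#'
#' Wadell sphericity: the surface area of a volume-equivalent sphere
#' divided by the object's surface area,
#' Psi = pi^(1/3) (6 V)^(2/3) / A, with V the voxel volume sum (mm^3) and
#' A (mm^2) the isosurface area estimated by projection-weighted face
#' counting (see [surface_area_mm2()]).
#'
#' @param voi mask (computed on the union of all components).
#' @param spacing voxel spacing in mm.
#' @return Psi; 1 for a sphere, lower for elongated or rough shapes.
#' @export
sphericity <- function(voi, spacing = NULL) {
  m <- mask_array(voi)
  if (sum(m) < 2) stop("sphericity needs at least two voxels")
  if (is.null(spacing))
    spacing <- if (inherits(voi, "voxel_mask")) voi$spacing else c(1, 1, 1)
  V <- sum(m) * prod(spacing)
  A <- surface_area_mm2(m, spacing)
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

#' Surface area of a binary mask
#'
#' Projection-weighted face counting: every exposed voxel face contributes
#' its face area times |n| / ||n||_1, where n is the local surface normal
#' estimated by central differences of the indicator at the two voxels
#' sharing the face.  By the projection (Cauchy) argument this estimator
#' is exact for planar boundaries of any orientation, so both curved and
#' axis-aligned flat surfaces are measured without the staircase bias of
#' plain face counting.
#'
#' @param mask logical 3D array or [voxel_mask()].
#' @param spacing voxel spacing in mm.
#' @return area in mm^2.
#' @export
surface_area_mm2 <- function(mask, spacing = c(1, 1, 1)) {
  f <- pad_array(mask_array(mask) * 1.0, 2)
  grads <- list(
    (shift_arr(f, 1, -1) - shift_arr(f, 1, 1)) / (2 * spacing[1]),
    (shift_arr(f, 2, -1) - shift_arr(f, 2, 1)) / (2 * spacing[2]),
    (shift_arr(f, 3, -1) - shift_arr(f, 3, 1)) / (2 * spacing[3]))
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  total <- 0
  for (ax in 1:3) for (dir in c(-1, 1)) {
    nb <- shift_arr(f, ax, -dir)
    faces <- which(f == 1 & nb == 0)
    if (!length(faces)) next
    n1 <- (grads[[1]][faces] + shift_arr(grads[[1]], ax, -dir)[faces]) / 2
    n2 <- (grads[[2]][faces] + shift_arr(grads[[2]], ax, -dir)[faces]) / 2
    n3 <- (grads[[3]][faces] + shift_arr(grads[[3]], ax, -dir)[faces]) / 2
    l2 <- sqrt(n1^2 + n2^2 + n3^2)
    l1 <- abs(n1) + abs(n2) + abs(n3)
    w <- ifelse(l2 > 1e-12, l2 / l1, 1)
    total <- total + sum(w) * face_area[ax]
  }
  total
}

pad_array <- function(a, n) {
  dm <- dim(a)
  out <- array(0, dm + 2 * n)
  out[n + seq_len(dm[1]), n + seq_len(dm[2]), n + seq_len(dm[3])] <- a
  out
}

# shift along axis by +1/-1 voxel, zero fill
shift_arr <- function(a, axis, by) {
  out <- array(0, dim(a))
  n <- dim(a)[axis]
  src <- lapply(dim(a), seq_len)
  dst <- src
  if (by == 1) { dst[[axis]] <- 2:n; src[[axis]] <- 1:(n - 1) }
  else { dst[[axis]] <- 1:(n - 1); src[[axis]] <- 2:n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}
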