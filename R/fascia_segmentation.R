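# Hierarchical 3D fascia segmentation: grade-dependent contrast and
# aggregation thresholds, potential-muscle classification, leg component
# selection, morphological compactification (VOI_IFA / FA), the local
# noise-adaptive candidate rule, the 26-direction ray-reflection shielding
# model, and the final morphological smoothing yielding VOI_IF.
#
# Masks are plain logical arrays inside this module; the pipeline wraps
# them into named voxel_mask objects.

#' Grade-dependent thresholds
#'
#' The operator grades the gross muscle appearance G in \{1, 2, 3\}
#' (3 = moth-eaten and washed-out).  The minimum contrast and minimum
#' aggregation are the linear functions
#' C_min = 0.75 - 0.15 G and alpha_min = 0.85 - 0.05 G.
#'
#' @param G integer grade, 1..3.
#' @return list with `G`, `c_min`, `alpha_min`.
#' @export
grade_params <- function(G) {
  if (length(G) != 1L || is.na(G) || !G %in% 1:3)
    stop("grade G must be in the range 1..3")
  list(G = as.integer(G), c_min = 0.75 - 0.15 * G,
       alpha_min = 0.85 - 0.05 * G)
}

#' Aggregation map
#'
#' For every voxel, the fraction of its 26 neighbours whose contrast is at
#' or above `c_min` (the Heaviside convention: ties pass).  Neighbours
#' outside the grid, or outside `valid` when given (e.g. the body mask),
#' count as failing.
#'
#' @param cmap contrast array from [contrast_map()].
#' @param c_min minimum contrast.
#' @param valid optional logical array of valid voxels.
#' @return numeric array of alpha values in \[0, 1\].
#' @export
aggregation_map <- function(cmap, c_min, valid = NULL) {
  if (is.null(valid)) valid <- array(TRUE, dim = dim(cmap))
  cnt <- cpp_count_neighbors_ge(cmap, c_min, mask_array(valid), dim(cmap))
  array(cnt / 26, dim = dim(cmap))
}

#' Classify potential muscle voxels
#'
#' A voxel is potential muscle iff (1) its Euclidean depth from the body
#' surface is at least `depth_min` voxels, (2) its 26-connected component
#' of condition-(3,4) survivors touches the 1-voxel dilation of the femur,
#' (3) its contrast is at least C_min and (4) its aggregation at least
#' alpha_min.
#'
#' @param cmap contrast array.
#' @param amap aggregation array.
#' @param gp grade parameters from [grade_params()].
#' @param femur_mask femur mask (logical array or [voxel_mask()]).
#' @param body_mask body mask.
#' @param config an `mls_config` list.
#' @return logical array.
#' @export
classify_potential_muscle <- function(cmap, amap, gp, femur_mask, body_mask,
                                      config = load_config()) {
  body <- mask_array(body_mask)
  s34 <- body & cmap >= gp$c_min & amap >= gp$alpha_min
  lab <- label_components(s34)
  femur_dil <- dilate_ball(femur_mask, config$femur_dilation)
  touching <- sort(unique(lab[femur_dil & lab > 0]))
  if (!length(touching))
    stop("no potential-muscle component connects to the femur; ",
         "consider a higher muscle-appearance grade G")
  kept <- array(lab %in% touching, dim = dim(lab))
  depth <- edt_sq(!body)          # squared depth, voxel units
  kept <- kept & depth >= config$depth_min^2
  if (!any(kept))
    stop("potential-muscle set is empty after the depth condition; ",
         "consider a higher muscle-appearance grade G")
  kept
}

#' Select the leg components
#'
#' Keeps the two largest 26-connected components of the potential-muscle
#' mask and labels them right/left by the x centre of mass relative to the
#' femur (patient right = lower x).  A single-leg image returns one
#' component with a warning.
#'
#' @param mask potential-muscle logical array.
#' @param femur_mask femur mask.
#' @return list with logical arrays `rc` (right) and `lc` (left; `NULL`
#'   for single-leg images).
#' @export
select_leg_components <- function(mask, femur_mask) {
  comps <- largest_components(mask, 2)
  if (!length(comps) || !any(comps[[1]]))
    stop("no connected components in the potential-muscle mask")
  com_x <- function(m) {
    w <- which(m) - 1L
    mean(w %% dim(m)[1])
  }
  if (length(comps) == 1L || !any(comps[[2]])) {
    warning("only one leg component found")
    fx <- com_x(mask_array(femur_mask))
    if (com_x(comps[[1]]) <= fx)
      return(list(rc = comps[[1]], lc = NULL))
    return(list(rc = NULL, lc = comps[[1]]))
  }
  xs <- vapply(comps, com_x, numeric(1))
  if (xs[1] <= xs[2]) list(rc = comps[[1]], lc = comps[[2]])
  else list(rc = comps[[2]], lc = comps[[1]])
}

#' Compactify a leg component into VOI_IFA
#'
#' Morphological closing with a z-elongated ellipsoidal structuring
#' element (the fascia is cylindrical and the muscles extend along the
#' leg axis) followed by per-slice contour filling.  The surface of the
#' result is the fascia approximation FA.
#'
#' @param component logical array (one leg's potential muscle).
#' @param config an `mls_config` list.
#' @return logical array VOI_IFA (always a superset of the input).
#' @export
compactify <- function(component, config = load_config()) {
  if (!any(mask_array(component))) stop("empty component")
  closed <- close_ellipsoid(component, config$closing_semiaxes)
  fill_cavities_slicewise(closed)
}

#' Dermis-connected set
#'
#' Voxels with contrast above 1 that are 26-connected to the thigh
#' surface; used to keep the dermis (and anything attached to it) out of
#' the fascia candidates and out of VOI_SAT.
#'
#' @param cmap contrast array.
#' @param body_mask body mask.
#' @return logical array.
#' @export
dermis_connected <- function(cmap, body_mask) {
  body <- mask_array(body_mask)
  # the thigh surface is the skin: axial truncation faces of the scan are
  # not surface, otherwise clipped muscle would seed the dermis set
  surf <- mask_boundary(body, z_edge = "inside")
  seeds <- surf & cmap > 1
  if (!any(seeds)) return(array(FALSE, dim = dim(body)))
  region_grow(cmap > 1, seeds)
}

#' Fascia candidate voxels
#'
#' Volume growing seeded on the FA surface: a voxel joins iff it lies
#' within `candidate_band` voxels (Euclidean) of FA, is not in the
#' dermis-connected set, and satisfies the predicate f: accept outright
#' when C > 1; for 0.5 <= C <= 1 apply the local noise-adaptive rule g
#' (accept iff HU >= mean26 - `g_sd_factor` * SD26 of the 26-neighbour HU,
#' ties pass); reject otherwise.
#'
#' @param vol a [ct_volume()].
#' @param cmap contrast array.
#' @param ifa VOI_IFA logical array (FA is its surface).
#' @param dermis dermis-connected logical array.
#' @param config an `mls_config` list.
#' @return list with `candidates` (logical array, disjoint from `ifa`) and
#'   `band` (logical array: within `candidate_band` of FA, including IFA).
#' @export
find_candidate_voxels <- function(vol, cmap, ifa, dermis,
                                  config = load_config()) {
  band_r <- config$candidate_band
  band <- edt_sq(ifa) <= band_r^2 + ball_tol
  ns <- neighborhood_stats(vol)
  g_ok <- vol$data >= ns$mean - config$g_sd_factor * ns$sd
  f_ok <- (cmap > 1) | (cmap >= 0.5 & cmap <= 1 & g_ok)
  accept <- band & !ifa & !dermis & f_ok
  fa <- mask_boundary(ifa)
  grown <- region_grow(accept, fa)
  list(candidates = grown & !ifa, band = band)
}

#' Ray-reflection shielding of fascia gaps
#'
#' From an operator seed placed in the space between FA and a candidate
#' conglomerate, the gap is grown through non-FA, non-candidate voxels of
#' the candidate band.  Every visited voxel casts rays in the 26 lattice
#' directions with unit voxel steps; a ray reflects if it reaches a
#' candidate or VOI_IFA voxel before travelling `candidate_band` voxels or
#' leaving the band.  A voxel is shielded when at least
#' ceil(`shielding_frac` * 26) rays (17 of 26 by default) reflect.
#'
#' @param ifa VOI_IFA logical array.
#' @param candidates candidate logical array.
#' @param band band logical array from [find_candidate_voxels()].
#' @param seeds 0-based (i, j, k) matrix, or a logical seed array.
#' @param config an `mls_config` list.
#' @return list of class `shielding_result`: `status` array (0 untested,
#'   1 not shielded, 2 shielded), `reflections` array (-1 untested),
#'   `shielded` logical array, `quorum`.
#' @export
ray_shielding <- function(ifa, candidates, band, seeds,
                          config = load_config()) {
  dm <- dim(mask_array(ifa))
  blocker <- mask_array(ifa) | mask_array(candidates)
  if (is.matrix(seeds)) {
    idx0 <- as.integer(linear_index(seeds, dm) - 1L)
  } else {
    idx0 <- which(mask_array(seeds)) - 1L
  }
  if (!length(idx0)) stop("no shielding seeds given")
  quorum <- as.integer(ceiling(config$shielding_frac * 26))
  res <- cpp_ray_shield(blocker, mask_array(band), idx0, dm, quorum,
                        config$candidate_band)
  status <- array(res$status, dim = dm)
  structure(list(status = status,
                 reflections = array(res$reflections, dim = dm),
                 shielded = status == 2L, quorum = quorum),
            class = "shielding_result")
}

#' Finalize the intrafascial VOI
#'
#' Merges VOI_IFA with the candidate voxels (minus operator-rejected
#' conglomerates) and the shielded voxels, contour-fills the remaining
#' enclosed gap voxels slice-wise, and smooths the union by a
#' morphological opening followed by closing with a
#' `smoothing_radius`-voxel ball, which removes porous or non-compact
#' unselected clusters.  The surface of VOI_IF is the fascia.
#'
#' @param ifa VOI_IFA logical array.
#' @param candidates candidate logical array.
#' @param shielded logical array (or `NULL` when there are no gaps).
#' @param rejected optional 0-based (i, j, k) matrix marking candidate
#'   conglomerates to exclude.
#' @param config an `mls_config` list.
#' @return list with `voi_if`, `fascia` (surface) and `filled` (contour-
#'   filled gap voxels) logical arrays.
#' @export
finalize_if <- function(ifa, candidates, shielded = NULL, rejected = NULL,
                        config = load_config()) {
  ifa <- mask_array(ifa)
  cand <- mask_array(candidates)
  if (!is.null(rejected) && nrow(rejected <- as.matrix(rejected))) {
    lab <- label_components(cand)
    drop <- unique(lab[linear_index(rejected, dim(lab))])
    drop <- drop[drop > 0]
    if (length(drop)) cand <- cand & !array(lab %in% drop, dim = dim(lab))
  }
  merged <- ifa | cand
  if (!is.null(shielded)) merged <- merged | mask_array(shielded)
  with_fill <- fill_cavities_slicewise(merged)
  filled <- with_fill & !merged
  r <- config$smoothing_radius
  voi_if <- close_ball(open_ball(with_fill, r), r)
  lab <- label_components(voi_if)
  if (max(lab) > 1L) {
    sizes <- sort(tabulate(lab), decreasing = TRUE)
    warning("VOI_IF is not a single 26-connected component; fragment sizes: ",
            paste(sizes, collapse = ", "))
  }
  list(voi_if = voi_if, fascia = mask_boundary(voi_if), filled = filled)
}
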