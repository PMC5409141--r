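# Subject-specific HU calibration: the adipose reference CT_AT, the
# AT/water contrast scale, the trimmed-histogram SAT threshold T_AT and
# the high-density-muscle threshold T_HDM = 35 HU + CT_H2O.

#' Estimate the adipose reference value CT_AT
#'
#' 26-connected volume growing restricted to the HU window
#' \[-190, -30\], seeded inside the surface sphere; CT_AT is the mean HU of
#' the grown adipose VOI.
#'
#' @param vol a [ct_volume()].
#' @param sphere_mask the surface sphere from [segment_thigh_surface()].
#' @param config an `mls_config` list.
#' @return list with `ct_at` (HU) and `voi_at` ([voxel_mask()]).
#' @export
estimate_ct_at <- function(vol, sphere_mask, config = load_config()) {
  stopifnot(inherits(vol, "ct_volume"))
  rng <- config$at_range
  in_range <- vol$data >= rng[1] & vol$data <= rng[2]
  seeds <- mask_array(sphere_mask) & in_range
  if (!any(seeds))
    stop("surface sphere contains no adipose-range voxels; ",
         "sphere likely misplaced")
  grown <- region_grow(in_range, seeds)
  if (sum(grown) < config$at_min_voxels)
    stop("grown adipose VOI has fewer than ", config$at_min_voxels,
         " voxels; sphere likely misplaced")
  list(ct_at = mean(vol$data[grown]),
       voi_at = voxel_mask(grown, vol, "VOI_AT"))
}

#' Water value from an ROI
#'
#' Mean HU over an in-scan calibration-phantom water insert ROI.
#'
#' @param vol a [ct_volume()].
#' @param roi a [voxel_mask()] inside the water insert.
#' @return CT_H2O in HU.
#' @export
ct_h2o_from_roi <- function(vol, roi) {
  m <- mask_array(roi)
  if (!any(m)) stop("water ROI is empty")
  mean(vol$data[m])
}

#' Calibration context
#'
#' Bundles the water value CT_H2O, the adipose reference CT_AT, the SAT
#' threshold T_AT and the high-density-muscle threshold
#' T_HDM = `hdm_constant` + CT_H2O.
#'
#' @param ct_h2o water HU.
#' @param ct_at adipose reference HU.
#' @param t_at SAT threshold (from [compute_t_at()]); may be `NA` before
#'   the SAT stage.
#' @param hdm_constant HU constant added to CT_H2O (default 35).
#' @return object of class `mls_calibration`.
#' @export
calibration_context <- function(ct_h2o, ct_at, t_at = NA_real_,
                                hdm_constant = 35) {
  t_hdm <- hdm_constant + ct_h2o
  if (ct_at >= ct_h2o)
    stop("calibration violated: CT_AT (", round(ct_at, 1),
         ") must be below CT_H2O (", round(ct_h2o, 1), ")")
  if (ct_h2o >= t_hdm)
    stop("calibration violated: CT_H2O must be below T_HDM")
  structure(list(ct_h2o = ct_h2o, ct_at = ct_at, t_at = t_at,
                 t_hdm = t_hdm, hdm_constant = hdm_constant),
            class = "mls_calibration")
}

#' @export
print.mls_calibration <- function(x, ...) {
  cat(sprintf(
    "<mls_calibration> CT_H2O = %.2f, CT_AT = %.2f, T_AT = %.2f, T_HDM = %.2f HU\n",
    x$ct_h2o, x$ct_at, x$t_at, x$t_hdm))
  invisible(x)
}

#' High-density-muscle threshold
#'
#' T_HDM = `hdm_constant` + CT_H2O (default constant 35 HU, derived from
#' the muscle tissue of young athletes).
#'
#' @param ct_h2o water HU.
#' @param hdm_constant HU constant.
#' @return T_HDM in HU.
#' @export
compute_t_hdm <- function(ct_h2o, hdm_constant = 35) hdm_constant + ct_h2o

#' Per-voxel contrast map
#'
#' Linear contrast C with C = 0 at the adipose reference CT_AT and C = 1
#' at the water value CT_H2O; unclamped, so dermis, bone and vessels map
#' above 1.
#'
#' @param vol a [ct_volume()].
#' @param ctx an [calibration_context()].
#' @return numeric 3D array.
#' @export
contrast_map <- function(vol, ctx) {
  den <- ctx$ct_h2o - ctx$ct_at
  if (den == 0) stop("degenerate contrast scale: CT_H2O equals CT_AT")
  (vol$data - ctx$ct_at) / den
}

#' 1-HU-bin histogram of a VOI
#'
#' @param vol a [ct_volume()].
#' @param mask a [voxel_mask()] or logical array.
#' @return list with integer bin `centers` (HU) and `counts`.
#' @export
hu_histogram <- function(vol, mask) {
  hu <- round(vol$data[mask_array(mask)])
  lo <- min(hu)
  counts <- tabulate(hu - lo + 1L, nbins = max(hu) - lo + 1L)
  list(centers = lo:max(hu), counts = counts)
}

hist_mean_sd <- function(centers, counts) {
  n <- sum(counts)
  mu <- sum(centers * counts) / n
  v <- sum(counts * (centers - mu)^2) / n
  c(mean = mu, sd = sqrt(v))
}

#' SAT threshold T_AT from the trimmed SAT spectrum
#'
#' The 1-HU histogram of the SAT VOI is trimmed at both tails where counts
#' fall below `hist_cut_frac` (default 30%) of the modal count (outermost
#' contiguous cut).  To obtain a symmetric spectrum SAT* unaffected by the
#' skew of residual contaminants, the lower half is discarded and the
#' upper half mirrored about the mode.  T_AT is the mean + `tat_sd_factor`
#' (default 2) SD of SAT*.
#'
#' @param vol a [ct_volume()].
#' @param sat_mask the SAT [voxel_mask()].
#' @param config an `mls_config` list.
#' @return list with `t_at` (HU) and `histogram` (class
#'   `trimmed_histogram`: centers, counts, mode, trim bounds, SAT* centers
#'   and counts, SAT* mean/SD).
#' @export
compute_t_at <- function(vol, sat_mask, config = load_config()) {
  if (!any(mask_array(sat_mask))) stop("SAT mask is empty")
  h <- hu_histogram(vol, sat_mask)
  tr <- trimmed_sat_star(h$centers, h$counts, config$hist_cut_frac,
                         config$tat_sd_factor)
  list(t_at = tr$t_at, histogram = tr)
}

# Direct computation of the trimmed, mirrored SAT* statistic from a
# histogram; shared by compute_t_at and usable as a standalone oracle
# input path.
trimmed_sat_star <- function(centers, counts, cut_frac = 0.30,
                             sd_factor = 2) {
  mode_i <- which.max(counts)
  thr <- cut_frac * counts[mode_i]
  lo <- 1L
  while (lo < mode_i && counts[lo] < thr) lo <- lo + 1L
  hi <- length(counts)
  while (hi > mode_i && counts[hi] < thr) hi <- hi - 1L
  if (hi - lo + 1L < 10L)
    stop("fewer than 10 histogram bins survive the 30% trim; ",
         "SAT spectrum too narrow or mask too small")
  cc <- centers[lo:hi]
  cn <- counts[lo:hi]
  m <- mode_i - lo + 1L
  # SAT*: upper half mirrored about the mode
  upper_off <- seq_len(length(cc) - m + 1L) - 1L   # offsets 0..(hi-m)
  star_centers <- c(rev(cc[m] - upper_off[-1]), cc[m] + upper_off)
  star_counts <- c(rev(cn[m + upper_off[-1]]), cn[m + upper_off])
  ms <- hist_mean_sd(star_centers, star_counts)
  structure(list(centers = cc, counts = cn, mode = cc[m],
                 trim_bounds = c(cc[1], cc[length(cc)]),
                 star_centers = star_centers, star_counts = star_counts,
                 star_mean = ms[["mean"]], star_sd = ms[["sd"]],
                 t_at = ms[["mean"]] + sd_factor * ms[["sd"]]),
            class = "trimmed_histogram")
}
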