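# Partition of VOI_US / VOI_IF into SAT, PAT, anatomical muscle M, muscle
# tissue MT, high-density muscle and muscle-concentration bins.

#' Segment the subcutaneous adipose tissue
#'
#' VOI_SAT = VOI_US minus VOI_IF minus everything connected with the
#' dermis; small residual fragments are dropped (components smaller than a
#' quarter of the largest, so one annulus per leg survives).
#'
#' @param voi_us analysis-slab logical array or [voxel_mask()].
#' @param voi_if intrafascial logical array.
#' @param dermis dermis-connected logical array from [dermis_connected()].
#' @return logical array.
#' @export
segment_sat <- function(voi_us, voi_if, dermis) {
  sat0 <- mask_array(voi_us) & !mask_array(voi_if) & !mask_array(dermis)
  if (!any(sat0)) stop("SAT is empty after subtracting VOI_IF and dermis")
  lab <- label_components(sat0)
  sizes <- tabulate(lab)
  keep <- which(sizes >= 0.25 * max(sizes))
  array(lab %in% keep, dim = dim(lab))
}

#' Segment perimuscular AT and anatomical muscle
#'
#' VOI_PAT is grown (26-connected) from fascia-adjacent interior voxels
#' whose HU is strictly below T_AT, under the assumption that PAT but not
#' EML is connected with the fascia.  VOI_M = VOI_IF minus VOI_PAT minus
#' the dilated femur; EML grains remain inside VOI_M by construction.
#'
#' @param vol a [ct_volume()].
#' @param voi_if intrafascial logical array.
#' @param fascia fascia-surface logical array (the boundary of VOI_IF).
#' @param t_at SAT threshold (HU) from [compute_t_at()].
#' @param femur_mask femur mask.
#' @param config an `mls_config` list.
#' @return list with logical arrays `pat`, `m` and `femur_dil`.
#' @export
segment_pat_and_m <- function(vol, voi_if, fascia, t_at, femur_mask,
                              config = load_config()) {
  voi_if <- mask_array(voi_if)
  femur_dil <- dilate_ball(femur_mask, config$femur_dilation)
  interior <- voi_if & !mask_array(fascia) & !femur_dil
  below <- vol$data < t_at
  seeds <- interior & below & dilate_ball(fascia, sqrt(3) + 1e-6)
  pat <- if (any(seeds)) region_grow(interior & below, seeds)
  else array(FALSE, dim = dim(voi_if))
  m <- voi_if & !pat & !femur_dil
  list(pat = pat, m = m, femur_dil = femur_dil)
}

#' Two-Gaussian decomposition of a tissue histogram
#'
#' Least-squares fit (Levenberg-Marquardt) of the sum of two Gaussians to
#' the 1-HU-bin histogram of a VOI (typically VOI_MLS = VOI_SAT + VOI_IF,
#' or VOI_IF).  The adipose component is initialized from the SAT*
#' spectrum (height, peak, width); the muscle component's height from the
#' voxel-count ratio of VOI_AT to the VOI scaled by the modal count, its
#' peak from the phantom-calibrated muscle value T_HDM.
#'
#' @param vol a [ct_volume()].
#' @param mask the VOI to decompose.
#' @param sat_star a `trimmed_histogram` from [compute_t_at()].
#' @param n_voi_at voxel count of VOI_AT (from [estimate_ct_at()]).
#' @param ctx an [calibration_context()].
#' @param config an `mls_config` list.
#' @return object of class `gmm_fit`: `at` and `mt` components (height,
#'   mean, sd), intersection `a`, muscle peak `b`, `resid_norm`,
#'   `converged`, and the fitted histogram.
#' @export
fit_gmm <- function(vol, mask, sat_star, n_voi_at, ctx,
                    config = load_config()) {
  m <- mask_array(mask)
  if (!any(m)) stop("cannot fit a mixture to an empty VOI")
  h <- hu_histogram(vol, m)
  x <- h$centers
  y <- h$counts
  at_init <- c(h = max(sat_star$star_counts), m = sat_star$star_mean,
               s = max(sat_star$star_sd, config$gmm_min_sd))
  mt_init <- c(h = max(1, n_voi_at / sum(m) * max(y)), m = ctx$t_hdm,
               s = config$gmm_mt_init_sd)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ h1 * exp(-(x - m1)^2 / (2 * s1^2)) +
        h2 * exp(-(x - m2)^2 / (2 * s2^2)),
      start = list(h1 = at_init[["h"]], m1 = at_init[["m"]],
                   s1 = at_init[["s"]], h2 = mt_init[["h"]],
                   m2 = mt_init[["m"]], s2 = mt_init[["s"]]),
      lower = c(0, min(x), config$gmm_min_sd, 0, min(x), config$gmm_min_sd),
      upper = c(Inf, max(x), diff(range(x)), Inf, max(x), diff(range(x))),
      control = minpack.lm::nls.lm.control(maxiter = config$gmm_max_iter)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(at = at_init, mt = mt_init, a = NA_real_,
                          b = NA_real_, resid_norm = NA_real_,
                          converged = FALSE, histogram = h),
                     class = "gmm_fit"))
  }
  p <- coef(fit)
  at <- c(h = p[["h1"]], m = p[["m1"]], s = p[["s1"]])
  mt <- c(h = p[["h2"]], m = p[["m2"]], s = p[["s2"]])
  if (at[["m"]] > mt[["m"]]) { tmp <- at; at <- mt; mt <- tmp }
  a <- gmm_intersection(at[["h"]], at[["m"]], at[["s"]],
                        mt[["h"]], mt[["m"]], mt[["s"]])
  conv <- isTRUE(fit$convInfo$isConv) && is.finite(a) &&
    a > at[["m"]] && a < mt[["m"]]
  structure(list(at = at, mt = mt, a = a, b = mt[["m"]],
                 resid_norm = sqrt(sum(residuals(fit)^2)),
                 converged = conv, histogram = h),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf(
    "<gmm_fit> AT: N(%.1f, %.1f^2) h=%.0f | MT: N(%.1f, %.1f^2) h=%.0f | a=%.2f b=%.2f (%s)\n",
    x$at[["m"]], x$at[["s"]], x$at[["h"]], x$mt[["m"]], x$mt[["s"]],
    x$mt[["h"]], x$a, x$b, if (x$converged) "converged" else "FLAGGED"))
  invisible(x)
}

#' Intersection of two Gaussian curves
#'
#' The HU value between the two means where
#' h1 N(m1, s1) = h2 N(m2, s2) (unnormalized Gaussians with heights h).
#' Closed form via the quadratic in HU obtained from equating the
#' log-densities; the root between the means is returned (NA when the
#' curves do not cross there).
#'
#' @param h1,m1,s1 height, mean, SD of the lower-mean component.
#' @param h2,m2,s2 height, mean, SD of the upper-mean component.
#' @return the intersection HU value.
#' @export
gmm_intersection <- function(h1, m1, s1, h2, m2, s2) {
  if (m1 > m2) stop("expected m1 <= m2")
  A <- 1 / (2 * s1^2) - 1 / (2 * s2^2)
  B <- m2 / s2^2 - m1 / s1^2
  C <- m1^2 / (2 * s1^2) - m2^2 / (2 * s2^2) - log(h1) + log(h2)
  roots <- if (abs(A) < 1e-12) {
    if (abs(B) < 1e-12) return(NA_real_)
    -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) return(NA_real_)
    (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  inside <- roots[roots >= m1 & roots <= m2]
  if (!length(inside)) NA_real_ else inside[1]
}

#' Segment muscle tissue
#'
#' 3D 26-connected volume growing inside VOI_IF (femur excluded) from
#' seed voxels at or above the muscle peak b, accepting voxels with HU
#' strictly above the intersection a of the two mixture components.
#'
#' @param vol a [ct_volume()].
#' @param voi_if intrafascial logical array.
#' @param fit a convergent [fit_gmm()] result.
#' @param femur_mask femur mask.
#' @param config an `mls_config` list.
#' @return logical array VOI_MT.
#' @export
segment_mt <- function(vol, voi_if, fit, femur_mask,
                       config = load_config()) {
  if (!inherits(fit, "gmm_fit") || !fit$converged)
    stop("muscle-tissue segmentation requires a convergent mixture fit")
  domain <- mask_array(voi_if) & !dilate_ball(femur_mask, config$femur_dilation)
  # ties pass at the peak; the histogram has 1-HU bins and the fitted b
  # carries optimizer-level error, so seed selection is tolerant to half
  # a bin (the acceptance threshold a is unaffected)
  seeds <- domain & vol$data >= fit$b - 0.5
  if (!any(seeds)) {
    warning("no seed voxels at or above the muscle peak; VOI_MT is empty")
    return(array(FALSE, dim = dim(domain)))
  }
  region_grow(domain & vol$data > fit$a, seeds)
}

#' Muscle-concentration bins
#'
#' Per-voxel muscle concentration 100 (HU - T_AT) / (T_HDM - T_AT) over
#' VOI_IF minus the (dilated) femur, floored to integer percent and
#' binned: IMAT below 0%, B2 0-24, B3 25-49, B4 50-74, B5 75-99 and
#' B6 (= HDM) at or above 100%.
#'
#' @param vol a [ct_volume()].
#' @param voi_if intrafascial logical array.
#' @param ctx an [calibration_context()] with `t_at` set.
#' @param femur_mask femur mask.
#' @param config an `mls_config` list.
#' @return list of class `concentration_map`: `concentration` (numeric
#'   array, NA outside the domain), `bin` (integer array: 0 outside,
#'   1 IMAT, 2..6 = B2..B6), `bin_names`, and masks `hdm`, `imat`.
#' @export
concentration_bins <- function(vol, voi_if, ctx, femur_mask,
                               config = load_config()) {
  if (!is.finite(ctx$t_at)) stop("calibration context lacks T_AT")
  if (ctx$t_at >= ctx$t_hdm) stop("T_AT must be below T_HDM")
  domain <- mask_array(voi_if) & !dilate_ball(femur_mask, config$femur_dilation)
  conc <- array(NA_real_, dim = dim(domain))
  conc[domain] <- 100 * (vol$data[domain] - ctx$t_at) / (ctx$t_hdm - ctx$t_at)
  cint <- floor(conc)
  bin <- array(0L, dim = dim(domain))
  bin[domain & cint < 0] <- 1L
  bin[domain & cint >= 0 & cint <= 24] <- 2L
  bin[domain & cint >= 25 & cint <= 49] <- 3L
  bin[domain & cint >= 50 & cint <= 74] <- 4L
  bin[domain & cint >= 75 & cint <= 99] <- 5L
  bin[domain & cint >= 100] <- 6L
  structure(list(concentration = conc, bin = bin,
                 bin_names = c("IMAT", "B2", "B3", "B4", "B5", "B6"),
                 hdm = bin == 6L, imat = bin == 1L),
            class = "concentration_map")
}
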