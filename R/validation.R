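# Validation harness: reanalysis precision (CV_RMS), cohort variation
# (CV_100), noise sensitivity and water-calibration sensitivity.

#' Root-mean-square coefficient of variation
#'
#' Precision error over repeated analyses:
#' CV_RMS = 100 sqrt( mean_j (SD_j / |mean_j|)^2 ) over subjects j, the
#' standard precision convention for imaging biomarkers.
#'
#' @param repeats numeric matrix (subjects x repeats), or a list of
#'   per-subject repeat vectors.
#' @return CV_RMS in percent.
#' @export
cv_rms <- function(repeats) {
  if (is.matrix(repeats)) repeats <- split(repeats, row(repeats))
  if (!length(repeats)) stop("no subjects")
  cvs <- vapply(repeats, function(x) {
    x <- as.numeric(x)
    if (length(x) < 2) stop("each subject needs at least 2 repeats")
    m <- mean(x)
    if (m == 0) stop("subject mean is zero; CV undefined")
    sd(x) / abs(m)
  }, numeric(1))
  100 * sqrt(mean(cvs^2))
}

#' Cohort variation CV_100
#'
#' The percentage coefficient of variation divided by 100 (i.e. SD/|mean|),
#' the scale against which reanalysis precision errors are compared.
#'
#' @param values per-subject feature values.
#' @return CV_100 (unitless).
#' @export
cv_100 <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 subjects")
  m <- mean(values)
  if (m == 0) stop("cohort mean is zero; CV undefined")
  (100 * sd(values) / abs(m)) / 100
}

#' Noise-sensitivity experiment
#'
#' Runs the full pipeline on the original volume and on a noise-augmented
#' copy with the identical replayed session (same grade, seeds and
#' calibration inputs), and reports the percent change of every feature,
#' rounded to one decimal.  Use [noise_sd_for_exposure_change()] to map an
#' exposure change to `sd_add` (doubling the noise at baseline SD sigma
#' requires adding sqrt(3) sigma).
#'
#' @param vol a [ct_volume()].
#' @param femur_mask femur [voxel_mask()].
#' @param session an [mls_session()].
#' @param sd_add SD of the Gaussian noise to add (HU).
#' @param noise_seed RNG seed for the added noise.
#' @param features optional roster subset passed to [run_features()].
#' @return data.frame with columns `voi`, `feature`, `value_orig`,
#'   `value_noisy`, `pct_change` (100 |delta| / |orig|, rounded to one
#'   decimal; NA when a value is missing).
#' @export
noise_experiment <- function(vol, femur_mask, session, sd_add,
                             noise_seed = 1L, features = NULL) {
  base <- run_segment(vol, femur_mask, session)
  f0 <- run_features(base, vol, features)
  noisy_vol <- add_gaussian_noise(vol, sd_add, seed = noise_seed)
  noisy <- tryCatch(run_segment(noisy_vol, femur_mask, session),
                    error = function(e) {
                      warning("segmentation failed on the noisy volume: ",
                              conditionMessage(e))
                      NULL
                    })
  f1 <- if (!is.null(noisy)) run_features(noisy, noisy_vol, features)
  out <- data.frame(voi = f0$voi, feature = f0$feature,
                    value_orig = f0$value,
                    value_noisy = if (is.null(f1)) NA_real_ else f1$value,
                    stringsAsFactors = FALSE)
  out$pct_change <- round(100 * abs(out$value_noisy - out$value_orig) /
                            abs(out$value_orig), 1)
  out
}

#' Water-calibration sensitivity experiment
#'
#' Re-evaluates the density features of a completed segmentation with the
#' water value shifted by +delta and -delta HU.  The segmentation masks
#' are held fixed except for the muscle-concentration bins (whose T_HDM
#' moves with CT_H2O, so the HDM and IMAT compartments are recomputed);
#' for every fixed-mask segmentation-based density the analytic
#' expectation of the change, 100 delta / |D|, is reported alongside.
#'
#' @param bundle an `mls_masks` bundle from [run_segment()].
#' @param vol the volume the bundle was computed from.
#' @param delta calibration shift in HU (nonzero).
#' @return data.frame with columns `voi`, `feature`, `value`,
#'   `value_plus`, `value_minus`, `pct_change_plus`, `pct_change_minus`
#'   (rounded to one decimal) and `pct_analytic` (NA where the mask itself
#'   moves with the calibration).
#' @export
calibration_experiment <- function(bundle, vol, delta = 5) {
  stopifnot(inherits(bundle, "mls_masks"))
  if (delta == 0) stop("delta must be nonzero")
  dens <- function(ctx_shift) {
    ctx <- bundle$ctx
    ctx2 <- calibration_context(ctx$ct_h2o + ctx_shift, ctx$ct_at, ctx$t_at,
                                ctx$hdm_constant)
    cfg <- bundle$session$config
    bins <- concentration_bins(vol, bundle$masks$VOI_IF$data, ctx2,
                               bundle$masks$femur_dil$data,
                               modifyList(cfg, list(femur_dilation = 0)))
    m <- bundle$masks
    vois <- list(SAT = m$VOI_SAT$data, IF = m$VOI_IF$data, M = m$VOI_M$data,
                 MT = m$VOI_MT$data, HDM = bins$hdm, IMAT = bins$imat)
    d <- vapply(vois, function(x)
      if (any(x)) density_hu(vol, x, ctx2) else NA_real_, numeric(1))
    g <- c(D_IF_GMM = if (bundle$gmm_if$converged)
      gmm_density(bundle$gmm_if, "mt", ctx2) else NA_real_,
      D_MLS_GMM = if (bundle$gmm_mls$converged)
        gmm_density(bundle$gmm_mls, "mt", ctx2) else NA_real_)
    list(d = d, g = g)
  }
  base <- dens(0); plus <- dens(delta); minus <- dens(-delta)
  fixed_mask <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)  # HDM/IMAT move
  out <- data.frame(
    voi = c(names(base$d), "MT", "MT"),
    feature = c(rep("D", length(base$d)), "D_IF_GMM", "D_MLS_GMM"),
    value = c(base$d, base$g),
    value_plus = c(plus$d, plus$g),
    value_minus = c(minus$d, minus$g),
    stringsAsFactors = FALSE)
  out$pct_change_plus <- round(100 * abs(out$value_plus - out$value) /
                                 abs(out$value), 1)
  out$pct_change_minus <- round(100 * abs(out$value_minus - out$value) /
                                  abs(out$value), 1)
  out$pct_analytic <- c(ifelse(fixed_mask, 100 * abs(delta) / abs(base$d), NA),
                        100 * abs(delta) / abs(base$g))
  out
}
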