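# End-to-end orchestration: analysis VOI -> calibration -> fascia ->
# compartments (run_segment) and the feature roster (run_features).
# Everything is driven by an mls_session, so a persisted session replays
# bit-identically.

#' Run the segmentation pipeline
#'
#' Executes surface segmentation, water/adipose calibration, the analysis
#' slab, hierarchical fascia segmentation (per leg), SAT/PAT/M/MT
#' compartments, the Gaussian-mixture fits of VOI_IF and VOI_MLS and the
#' muscle-concentration bins, entirely from the operator inputs recorded
#' in the session.
#'
#' @param vol a [ct_volume()].
#' @param femur_mask a [voxel_mask()] of the femur (a prior input).
#' @param session an [mls_session()].
#' @return a list of class `mls_masks`: named [voxel_mask()]s (`body`,
#'   `VOI_US`, `VOI_AT`, `VOI_IFA`, `candidates`, `VOI_IF`, `fascia`,
#'   `dermis`, `VOI_SAT`, `VOI_PAT`, `VOI_M`, `VOI_MT`, `VOI_MLS`, `HDM`,
#'   `IMAT`), the calibration context `ctx`, mixture fits `gmm_if` and
#'   `gmm_mls`, the concentration map `bins`, shielding diagnostics, and
#'   the session.
#' @export
run_segment <- function(vol, femur_mask, session) {
  stopifnot(inherits(vol, "ct_volume"))
  if (is.null(femur_mask)) stop("a femur mask is required")
  check_same_grid(voxel_mask(array(TRUE, dim(vol$data)), vol), femur_mask)
  if (!inherits(session, "mls_session")) stop("`session` must be an mls_session")
  cfg <- session$config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  surf <- stage("surface", segment_thigh_surface(vol, femur_mask, config = cfg))
  ct_h2o <- if (!is.null(session$ct_h2o)) session$ct_h2o
  else if (!is.null(session$water_roi))
    stage("calibration", ct_h2o_from_roi(vol, session$water_roi))
  else stop("session provides neither ct_h2o nor a water ROI")
  at <- stage("calibration", estimate_ct_at(vol, surf$sphere, cfg))
  ctx0 <- calibration_context(ct_h2o, at$ct_at, hdm_constant = cfg$hdm_constant)
  cmap <- contrast_map(vol, ctx0)

  if (is.null(session$n_slices))
    stop("session lacks n_slices (use compute_anatomic_frame() or set it)")
  voi_us <- stage("analysis VOI",
                  define_voi_us(surf$body, session$proximal_slice,
                                session$n_slices))

  gp <- grade_params(session$grade)
  amap <- aggregation_map(cmap, gp$c_min, valid = surf$body$data)
  pm <- stage("potential muscle",
              classify_potential_muscle(cmap, amap, gp, femur_mask,
                                        surf$body, cfg)) & voi_us$data
  legs <- stage("leg components", select_leg_components(pm, femur_mask))
  dermis <- dermis_connected(cmap, surf$body)

  gap_seeds <- as.matrix(session$seeds[session$seeds$role == "gap",
                                       c("i", "j", "k")])
  rejects <- as.matrix(session$seeds[session$seeds$role == "reject",
                                     c("i", "j", "k")])
  dm <- dim(vol$data)

  per_leg <- function(comp) {
    ifa <- compactify(comp, cfg)
    fc <- find_candidate_voxels(vol, cmap, ifa, dermis, cfg)
    shield <- NULL
    if (nrow(gap_seeds)) {
      lin <- linear_index(gap_seeds, dm)
      usable <- fc$band[lin] & !ifa[lin] & !fc$candidates[lin]
      if (any(usable))
        shield <- ray_shielding(ifa, fc$candidates, fc$band,
                                gap_seeds[usable, , drop = FALSE], cfg)
    }
    fin <- finalize_if(ifa, fc$candidates,
                       if (!is.null(shield)) shield$shielded,
                       rejected = if (nrow(rejects)) rejects,
                       config = cfg)
    list(ifa = ifa, candidates = fc$candidates, shield = shield, fin = fin)
  }

  comps <- Filter(Negate(is.null), legs[c("rc", "lc")])
  res <- stage("fascia", lapply(comps, per_leg))

  or_all <- function(get) {
    out <- array(FALSE, dim = dm)
    for (r in res) {
      v <- get(r)
      if (!is.null(v)) out <- out | v
    }
    out
  }
  voi_ifa <- or_all(function(r) r$ifa)
  candidates <- or_all(function(r) r$candidates)
  shielded <- or_all(function(r) if (!is.null(r$shield)) r$shield$shielded)
  voi_if <- or_all(function(r) r$fin$voi_if)

  # restrict the analysis to the slab slices
  slab <- array(FALSE, dim = dm)
  k0 <- session$proximal_slice + 1L
  k1 <- min(dm[3], session$proximal_slice + session$n_slices)
  slab[, , k0:k1] <- TRUE
  voi_if <- voi_if & slab
  # the fascia is the lateral surface of VOI_IF; the axial cut faces of
  # the analysis slab are not fascia
  fascia <- mask_boundary(voi_if, z_edge = "ignore")

  sat <- stage("SAT", segment_sat(voi_us$data, voi_if, dermis))
  tat <- tryCatch(compute_t_at(vol, sat, cfg), error = function(e) NULL)
  if (is.null(tat)) {
    # degenerate (near single-bin) SAT spectrum: fall back to the midpoint
    # of the contrast scale and a pseudo SAT* built from raw moments
    hu <- vol$data[sat]
    star <- structure(list(star_counts = length(hu), star_mean = mean(hu),
                           star_sd = max(sd(hu), cfg$gmm_min_sd)),
                      class = "trimmed_histogram")
    tat <- list(t_at = (at$ct_at + ct_h2o) / 2, histogram = star)
  }
  ctx <- calibration_context(ct_h2o, at$ct_at, tat$t_at, cfg$hdm_constant)

  patm <- stage("PAT/M", segment_pat_and_m(vol, voi_if, fascia, ctx$t_at,
                                           femur_mask, cfg))
  voi_mls <- sat | voi_if
  n_at <- sum(at$voi_at$data)
  gmm_mls <- stage("GMM", fit_gmm(vol, voi_mls, tat$histogram, n_at, ctx, cfg))
  gmm_if <- stage("GMM", fit_gmm(vol, voi_if, tat$histogram, n_at, ctx, cfg))
  mt <- stage("MT", segment_mt(vol, voi_if, gmm_mls, femur_mask, cfg))
  bins <- stage("bins", concentration_bins(vol, voi_if, ctx, femur_mask, cfg))

  mk <- function(arr, name) voxel_mask(arr, vol, name)
  structure(list(
    masks = list(
      body = surf$body, sphere = surf$sphere,
      VOI_US = voi_us, VOI_AT = at$voi_at,
      VOI_IFA = mk(voi_ifa, "VOI_IFA"),
      candidates = mk(candidates, "candidates"),
      shielded = mk(shielded, "shielded"),
      VOI_IF = mk(voi_if, "VOI_IF"),
      fascia = mk(fascia, "fascia"),
      dermis = mk(dermis, "dermis"),
      VOI_SAT = mk(sat, "VOI_SAT"),
      VOI_PAT = mk(patm$pat, "VOI_PAT"),
      VOI_M = mk(patm$m, "VOI_M"),
      VOI_MT = mk(mt, "VOI_MT"),
      VOI_MLS = mk(voi_mls, "VOI_MLS"),
      HDM = mk(bins$hdm, "HDM"),
      IMAT = mk(bins$imat, "IMAT"),
      femur_dil = mk(patm$femur_dil, "femur_dil")),
    ctx = ctx, t_surf = surf$t_surf, gmm_if = gmm_if, gmm_mls = gmm_mls,
    bins = bins, shielding = lapply(res, `[[`, "shield"),
    session = session), class = "mls_masks")
}

# feature x VOI applicability matrix of the reported roster
feature_roster <- function() {
  list(
    D = c("VOI_SAT", "VOI_IF", "VOI_M", "VOI_MT", "HDM", "IMAT"),
    D_IF_GMM = "VOI_MT",
    D_MLS_GMM = "VOI_MT",
    rV_IF = c("VOI_M", "VOI_MT", "HDM", "IMAT"),
    rV_MLS = c("VOI_SAT", "VOI_IF"),
    G_avg = c("VOI_MT", "HDM", "IMAT"),
    FD = c("VOI_IF", "VOI_M", "VOI_MT"),
    Psi = c("VOI_M", "VOI_MT"))
}

voi_display <- c(VOI_SAT = "SAT", VOI_IF = "IF", VOI_M = "M", VOI_MT = "MT",
                 HDM = "HDM", IMAT = "IMAT")

#' Compute the feature table
#'
#' Evaluates the reported feature roster (density D, GMM densities,
#' relative volumes, average grain size, fractal dimension, sphericity)
#' over the applicable VOIs of a segmentation bundle.  A failing or empty
#' VOI yields a missing value, not an error.
#'
#' @param bundle an `mls_masks` bundle from [run_segment()].
#' @param vol the [ct_volume()] the bundle was computed from.
#' @param features optional character vector restricting the roster
#'   (e.g. `c("D", "rV_IF", "rV_MLS")`).
#' @return data.frame of class `mls_features` with columns `voi`,
#'   `feature`, `value`, `units`.
#' @export
run_features <- function(bundle, vol, features = NULL) {
  stopifnot(inherits(bundle, "mls_masks"))
  roster <- feature_roster()
  if (!is.null(features)) roster <- roster[intersect(names(roster), features)]
  m <- bundle$masks
  ctx <- bundle$ctx
  rows <- list()
  val <- function(expr) tryCatch(expr, error = function(e) NA_real_,
                                 warning = function(w) suppressWarnings(expr))
  for (feat in names(roster)) for (voi in roster[[feat]]) {
    v <- switch(feat,
      D = val(density_hu(vol, m[[voi]], ctx)),
      D_IF_GMM = val(gmm_density(bundle$gmm_if, "mt", ctx)),
      D_MLS_GMM = val(gmm_density(bundle$gmm_mls, "mt", ctx)),
      rV_IF = val(relative_volume(m[[voi]], m$VOI_IF)),
      rV_MLS = val(relative_volume(m[[voi]], m$VOI_MLS)),
      G_avg = val(granulometry_avg(m[[voi]])),
      FD = val(fractal_dimension(m[[voi]])),
      Psi = val(sphericity(m[[voi]])))
    units <- switch(feat, D = , D_IF_GMM = , D_MLS_GMM = "HU",
                    G_avg = "mm", "")
    rows[[length(rows) + 1L]] <- data.frame(
      voi = voi_display[[voi]], feature = feat, value = v, units = units,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "calibration") <- unclass(ctx)
  class(out) <- c("mls_features", class(out))
  out
}

#' Write a feature table as CSV
#'
#' The calibration context is echoed in comment lines of the header.
#'
#' @param features an `mls_features` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  ctx <- attr(features, "calibration")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(ctx))
    writeLines(sprintf("# %s = %s", names(ctx), unlist(ctx)), con)
  write.csv(as.data.frame(features), con, row.names = FALSE)
  invisible(path)
}
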