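# Pipeline configuration: every printed constant of the method lives here
# and can be overridden from a JSON/YAML file or programmatically.

config_defaults <- function() {
  list(
    surface_threshold_frac = 0.70,  # skin threshold: fraction of sphere HU range
    surface_sphere_radius  = 10,    # voxels
    at_range               = c(-190, -30),  # HU window for SAT volume growing
    at_min_voxels          = 500,   # sanity floor for the grown VOI_AT
    depth_min              = 10,    # voxels, condition 1 of potential muscle
    candidate_band         = 15,    # voxels, Euclidean distance from FA
    shielding_frac         = 0.65,  # quorum fraction of 26 rays
    hist_cut_frac          = 0.30,  # tail cut at 30% of the modal count
    hdm_constant           = 35,    # HU, T_HDM = hdm_constant + CT_H2O
    tat_sd_factor          = 2,     # T_AT = mean + 2 SD of SAT*
    g_sd_factor            = 2,     # local adaptive rule: HU >= mean26 - 2 SD26
    closing_semiaxes       = c(5, 5, 10),  # voxels, compactification ellipsoid
    smoothing_radius       = 2,     # voxels, opening+closing ball of finalize_if
    femur_dilation         = 1,     # voxels, cortical partial-volume guard
    gmm_max_iter           = 200,
    gmm_min_sd             = 0.5,   # HU, lower bound for fitted widths
    gmm_mt_init_sd         = 15     # HU, initial width of the muscle component
  )
}

config_ranges <- list(
  surface_threshold_frac = c(0, 1),
  surface_sphere_radius  = c(1, 100),
  at_min_voxels          = c(1, Inf),
  depth_min              = c(0, 100),
  candidate_band         = c(1, 100),
  shielding_frac         = c(0, 1),
  hist_cut_frac          = c(0, 1),
  tat_sd_factor          = c(0, 10),
  g_sd_factor            = c(0, 10),
  smoothing_radius       = c(0, 20),
  femur_dilation         = c(0, 10),
  gmm_max_iter           = c(1, 1e5),
  gmm_min_sd             = c(1e-3, 100),
  gmm_mt_init_sd         = c(1e-3, 200)
)

#' Load the pipeline configuration
#'
#' Returns the full default parameter set with optional overrides from a
#' JSON or YAML file and/or an `overrides` list.  Unknown keys and
#' out-of-range values are rejected with the permissible range.
#'
#' @param path optional JSON (`.json`) or YAML (`.yml`/`.yaml`) file; an
#'   empty or missing file yields the defaults.
#' @param overrides named list applied after the file.
#' @param quiet suppress the effective-configuration message.
#' @return a named list of class `mls_config`.
#' @export
load_config <- function(path = NULL, overrides = list(), quiet = TRUE) {
  cfg <- config_defaults()
  from_file <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    if (grepl("\\.ya?ml$", tolower(path))) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("the 'yaml' package is required to read YAML configs")
      from_file <- yaml::read_yaml(path) %||% list()
    } else {
      txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
      from_file <- if (nzchar(trimws(txt)))
        jsonlite::fromJSON(txt, simplifyVector = TRUE) else list()
    }
  }
  for (ov in list(from_file, overrides)) {
    if (!length(ov)) next
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, ov)
  }
  validate_config(cfg)
  if (!quiet)
    message("effective config: ",
            jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
  structure(cfg, class = c("mls_config", "list"))
}

validate_config <- function(cfg) {
  for (key in names(config_ranges)) {
    r <- config_ranges[[key]]
    v <- cfg[[key]]
    if (!is.numeric(v) || any(v < r[1] | v > r[2]))
      stop(sprintf("config '%s' = %s outside the permissible range [%g, %g]",
                   key, paste(v, collapse = ","), r[1], r[2]))
  }
  if (length(cfg$at_range) != 2L || cfg$at_range[1] >= cfg$at_range[2])
    stop("config 'at_range' must be an increasing HU interval")
  if (length(cfg$closing_semiaxes) != 3L || any(cfg$closing_semiaxes <= 0))
    stop("config 'closing_semiaxes' must be three positive semi-axes (voxels)")
  invisible(cfg)
}
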