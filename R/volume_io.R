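# CT volume and mask containers plus file IO.
#
# Conventions fixed here and asserted at every module boundary:
# voxel indices are 0-based (i, j, k), the slice (scanner z) axis is the
# last array index, arrays are column-major with dim = c(nx, ny, nz).

#' Construct a CT volume
#'
#' A `ct_volume` is a 3D array of Hounsfield units (HU) together with its
#' voxel spacing in mm per axis and a world origin.  The slice (scanner z)
#' axis is the third array index.
#'
#' @param data 3D numeric array of HU values.
#' @param spacing numeric length-3, mm per voxel along (x, y, z); must be
#'   strictly positive.
#' @param origin numeric length-3, world coordinate of voxel (0,0,0) in mm.
#' @param check_range if `TRUE`, emit a warning (not an error) when values
#'   fall outside the plausible clinical range \[-1100, 3100\] HU.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      check_range = TRUE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  storage.mode(data) <- "double"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm/voxel)")
  if (any(!is.finite(data)))
    stop("HU values must be finite")
  if (isTRUE(check_range) && (min(data) < -1100 || max(data) > 3100))
    warning("HU values outside the plausible range [-1100, 3100]")
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' Construct a named voxel mask
#'
#' A `voxel_mask` is a binary grid aligned with a reference [ct_volume()]
#' (same shape and spacing).  Masks carry a name (e.g. `"VOI_SAT"`) so
#' they can be tracked through the pipeline and serialized.
#'
#' @param data logical (or coercible) 3D array.
#' @param reference a `ct_volume` or another `voxel_mask` providing the
#'   grid geometry.
#' @param name mask name.
#' @return an object of class `voxel_mask`.
#' @export
voxel_mask <- function(data, reference, name = "mask") {
  if (is.numeric(data)) data <- array(data != 0, dim = dim(data))
  if (!is.array(data) || length(dim(data)) != 3L || !is.logical(data))
    stop("`data` must be a logical 3D array")
  geom <- mask_geometry(reference)
  if (!identical(dim(data), geom$dim))
    stop(sprintf("mask '%s' shape (%s) does not match the reference grid (%s)",
                 name, paste(dim(data), collapse = "x"),
                 paste(geom$dim, collapse = "x")))
  structure(list(data = data, spacing = geom$spacing, name = name),
            class = "voxel_mask")
}

mask_geometry <- function(x) {
  if (inherits(x, "ct_volume") || inherits(x, "voxel_mask"))
    list(dim = dim(x$data), spacing = x$spacing)
  else if (is.array(x) && length(dim(x)) == 3L)
    list(dim = dim(x), spacing = c(1, 1, 1))
  else stop("reference must be a ct_volume, voxel_mask or 3D array")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> '%s': %d of %s voxels (%.2f%%)\n",
              x$name, sum(x$data), paste(dim(x$data), collapse = "x"),
              100 * mean(x$data)))
  invisible(x)
}

#' @export
dim.voxel_mask <- function(x) dim(x$data)

#' Number of voxels in a mask
#' @param mask a `voxel_mask` or logical array.
#' @return integer voxel count.
#' @export
mask_count <- function(mask) sum(mask_array(mask))

#' Physical volume of a mask in cubic millimetres
#' @param mask a `voxel_mask`.
#' @return volume in mm^3.
#' @export
mask_volume_mm3 <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  sum(mask$data) * prod(mask$spacing)
}

mask_array <- function(x) {
  if (inherits(x, "voxel_mask")) x$data
  else if (is.logical(x) && is.array(x)) x
  else stop("expected a voxel_mask or logical array")
}

# set algebra on aligned masks / logical arrays
check_same_grid <- function(a, b) {
  if (!identical(dim(mask_array(a)), dim(mask_array(b))))
    stop("masks are not on the same grid")
}

#' Mask set algebra
#'
#' Union, intersection and difference of masks on a common grid.
#' Inputs may be `voxel_mask` objects or plain logical arrays; a plain
#' logical array is returned.
#'
#' @param a,b masks.
#' @return logical array.
#' @export
mask_union <- function(a, b) { check_same_grid(a, b); mask_array(a) | mask_array(b) }

#' @rdname mask_union
#' @export
mask_intersect <- function(a, b) { check_same_grid(a, b); mask_array(a) & mask_array(b) }

#' @rdname mask_union
#' @export
mask_diff <- function(a, b) { check_same_grid(a, b); mask_array(a) & !mask_array(b) }

#' Dice overlap coefficient of two masks
#' @param a,b masks on one grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  check_same_grid(a, b)
  a <- mask_array(a); b <- mask_array(b)
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Read a CT volume
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`), MetaImage (`.mha`,
#' `.mhd`) and an uncompressed explicit-VR little-endian DICOM series
#' (a directory).
#'
#' @param path file or directory path.
#' @return a [ct_volume()].
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1:3]
    ct_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing = sp,
              check_range = FALSE)
  } else if (grepl("\\.mh[ad]$", lower)) {
    read_metaimage(path)
  } else {
    stop("unknown volume format: ", path,
         " (supported: .nii, .nii.gz, .mha, .mhd, DICOM directory)")
  }
}

#' Write a CT volume or mask
#'
#' NIfTI and MetaImage are supported.  Masks are written as unsigned
#' 8-bit, volumes as 32-bit float.
#'
#' @param x a [ct_volume()] or [voxel_mask()].
#' @param path output path ending in `.nii`, `.nii.gz`, `.mha` or `.mhd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  is_mask <- inherits(x, "voxel_mask")
  if (!is_mask && !inherits(x, "ct_volume"))
    stop("`x` must be a ct_volume or voxel_mask")
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    dat <- if (is_mask) array(as.integer(x$data), dim = dim(x$data)) else x$data
    attr(dat, "pixdim") <- x$spacing
    img <- RNifti::asNifti(dat, datatype = if (is_mask) "uint8" else "float")
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mh[ad]$", lower)) {
    write_metaimage(x, path, type = if (is_mask) "MET_UCHAR" else "MET_FLOAT")
  } else {
    stop("unknown output format: ", path)
  }
  invisible(path)
}

# ---- MetaImage ------------------------------------------------------------

meta_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
                MET_INT = 4L, MET_UINT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("MetaImage header without ElementDataFile")
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("malformed MetaImage header line: ", line)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != 3L) stop("only 3D MetaImage volumes are supported")
  sp <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  type <- hdr$ElementType
  if (!type %in% names(meta_sizes)) stop("unsupported ElementType: ", type)
  n <- prod(dims)
  read_raw <- function(con) {
    signed <- !type %in% c("MET_UCHAR", "MET_USHORT", "MET_UINT")
    what <- if (type %in% c("MET_FLOAT", "MET_DOUBLE")) "double" else "integer"
    readBin(con, what = what, n = n, size = meta_sizes[[type]],
            signed = if (what == "integer" && meta_sizes[[type]] < 4) signed else TRUE,
            endian = "little")
  }
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    vals <- read_raw(con)
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    con2 <- file(rawpath, "rb")
    on.exit(close(con2), add = TRUE)
    vals <- read_raw(con2)
  }
  ct_volume(array(as.numeric(vals), dim = dims), spacing = sp,
            check_range = FALSE)
}

write_metaimage <- function(x, path, type = "MET_FLOAT") {
  dat <- if (inherits(x, "voxel_mask")) as.integer(x$data) else as.numeric(x$data)
  local <- grepl("\\.mha$", tolower(path))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(x$data), collapse = " ")),
           paste("ElementSpacing =", paste(format(x$spacing, digits = 10), collapse = " ")),
           paste("ElementType =", type))
  write_data <- function(con) {
    if (type == "MET_FLOAT") writeBin(as.numeric(dat), con, size = 4L, endian = "little")
    else if (type == "MET_DOUBLE") writeBin(as.numeric(dat), con, size = 8L, endian = "little")
    else if (type == "MET_UCHAR") writeBin(as.raw(dat), con)
    else if (type == "MET_SHORT") writeBin(as.integer(dat), con, size = 2L, endian = "little")
    else stop("unsupported ElementType for writing: ", type)
  }
  if (local) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con)
    write_data(con)
  } else {
    rawname <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    writeLines(c(hdr, paste("ElementDataFile =", rawname)), path)
    con <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(con))
    write_data(con)
  }
  invisible(path)
}

# ---- minimal DICOM series reader ------------------------------------------
# Uncompressed explicit-VR little-endian single-frame CT slices only; the
# subset needed to assemble an HU volume (rescale slope/intercept applied).

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  u32 <- function(at) u16(at) + 65536 * u16(at + 2L)
  elems <- list()
  long_vr <- c("OB", "OW", "OF", "OD", "SQ", "UT", "UN")
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vr) {
      len <- u32(pos + 8L); hdr <- 12L
    } else {
      len <- u16(pos + 6L); hdr <- 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements are not supported")
    tag <- sprintf("%04x,%04x", group, elem)
    start <- pos + hdr
    elems[[tag]] <- list(vr = vr, start = start, len = len)
    pos <- start + len
  }
  val_str <- function(tag) {
    e <- elems[[tag]]
    if (is.null(e)) return(NULL)
    trimws(rawToChar(raw[e$start:(e$start + e$len - 1L)]))
  }
  val_u16 <- function(tag) {
    e <- elems[[tag]]
    if (is.null(e)) return(NULL)
    u16(e$start)
  }
  rows <- val_u16("0028,0010"); cols <- val_u16("0028,0011")
  if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns in ", path)
  bits <- val_u16("0028,0100")
  if (!identical(bits, 16L)) stop("only 16-bit DICOM pixel data is supported")
  signed <- identical(val_u16("0028,0103"), 1L)
  slope <- as.numeric(val_str("0028,1053")); if (!length(slope)) slope <- 1
  inter <- as.numeric(val_str("0028,1052")); if (!length(inter)) inter <- 0
  spacing <- as.numeric(strsplit(val_str("0028,0030") %||% "1\\1", "\\\\")[[1]])
  thick <- as.numeric(val_str("0018,0050") %||% "1")
  ipp <- as.numeric(strsplit(val_str("0020,0032") %||% "0\\0\\0", "\\\\")[[1]])
  px <- elems[["7fe0,0010"]]
  if (is.null(px)) stop("missing PixelData in ", path)
  con <- rawConnection(raw[px$start:(px$start + px$len - 1L)])
  on.exit(close(con))
  vals <- readBin(con, "integer", n = rows * cols, size = 2L,
                  signed = signed, endian = "little")
  list(pixels = matrix(vals * slope + inter, nrow = cols, ncol = rows),
       spacing = spacing, thickness = thick, z = ipp[3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no files in DICOM directory: ", dir)
  slices <- lapply(files, read_dicom_file)
  ord <- order(vapply(slices, `[[`, numeric(1), "z"))
  slices <- slices[ord]
  nx <- nrow(slices[[1]]$pixels); ny <- ncol(slices[[1]]$pixels)
  arr <- array(0, dim = c(nx, ny, length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]$pixels
  zs <- vapply(slices, `[[`, numeric(1), "z")
  dz <- if (length(zs) > 1) stats::median(diff(zs)) else slices[[1]]$thickness
  # DICOM PixelSpacing is (row, column) = (dy, dx)
  sp <- c(slices[[1]]$spacing[2], slices[[1]]$spacing[1], dz)
  ct_volume(arr, spacing = sp, check_range = FALSE)
}

# ---- seeds and sessions ---------------------------------------------------

#' Create a seed set
#'
#' Operator-provided voxel coordinates.  Roles: `"gap"` for fascia-gap
#' shielding seeds, `"reject"` for rejected candidate-conglomerate markers.
#'
#' @param coords integer matrix with columns (i, j, k), 0-based.
#' @param role character vector recycled over rows.
#' @param grid_dim optional grid dimensions for bounds checking.
#' @return data.frame with columns i, j, k, role.
#' @export
seed_set <- function(coords, role = "gap", grid_dim = NULL) {
  coords <- matrix(as.integer(coords), ncol = 3)
  role <- rep_len(as.character(role), nrow(coords))
  if (!all(role %in% c("gap", "reject")))
    stop("seed role must be 'gap' or 'reject'")
  if (!is.null(grid_dim)) {
    ok <- coords[, 1] >= 0 & coords[, 1] < grid_dim[1] &
      coords[, 2] >= 0 & coords[, 2] < grid_dim[2] &
      coords[, 3] >= 0 & coords[, 3] < grid_dim[3]
    if (!all(ok)) stop("seed coordinates outside the grid")
  }
  data.frame(i = coords[, 1], j = coords[, 2], k = coords[, 3], role = role,
             stringsAsFactors = FALSE)
}

# 0-based (i,j,k) matrix -> 1-based linear indices
linear_index <- function(coords, dm) {
  coords <- matrix(as.integer(coords), ncol = 3)
  1L + coords[, 1] + dm[1] * (coords[, 2] + dm[2] * coords[, 3])
}

#' Create an analysis session
#'
#' A session records every operator input so any segmentation can be
#' replayed non-interactively: the muscle-appearance grade, shielding
#' seeds and rejected conglomerates, the proximal (acetabulum end) slice,
#' the slab slice count, the water calibration value and any configuration
#' overrides.  Replaying a session on the same inputs reproduces all
#' masks bit-exactly.
#'
#' @param grade muscle-appearance grade G in \{1, 2, 3\}.
#' @param seeds a [seed_set()] data.frame (may be empty).
#' @param proximal_slice 0-based index of the most proximal slab slice.
#' @param n_slices number of slab slices (from [compute_anatomic_frame()]
#'   or operator input).
#' @param ct_h2o water HU, or `NULL` to estimate it from `water_roi`.
#' @param water_roi optional `voxel_mask` of the in-scan phantom water
#'   insert used when `ct_h2o` is `NULL`.
#' @param config a config list from [load_config()]; defaults used if `NULL`.
#' @return an object of class `mls_session`.
#' @export
mls_session <- function(grade, seeds = seed_set(matrix(integer(0), ncol = 3)),
                        proximal_slice = 0L, n_slices = NULL,
                        ct_h2o = NULL, water_roi = NULL, config = NULL) {
  if (!length(grade) == 1L || !grade %in% 1:3)
    stop("grade G must be 1, 2 or 3")
  structure(list(grade = as.integer(grade), seeds = seeds,
                 proximal_slice = as.integer(proximal_slice),
                 n_slices = if (!is.null(n_slices)) as.integer(n_slices),
                 ct_h2o = ct_h2o, water_roi = water_roi,
                 config = config %||% load_config()),
            class = "mls_session")
}

#' Persist / restore a session as JSON
#'
#' The water ROI, if present, is stored as 0-based voxel coordinates.
#'
#' @param session an [mls_session()].
#' @param path JSON file path.
#' @return `read_session` returns an `mls_session`; grid geometry for the
#'   water ROI must be re-attached via `grid_dim`/`spacing`.
#' @param grid_dim,spacing grid geometry used to reconstruct the water ROI.
#' @export
write_session <- function(session, path) {
  x <- list(grade = session$grade,
            seeds = session$seeds,
            proximal_slice = session$proximal_slice,
            n_slices = session$n_slices,
            ct_h2o = session$ct_h2o,
            config = session$config)
  if (!is.null(session$water_roi)) {
    w <- which(session$water_roi$data) - 1L
    dm <- dim(session$water_roi$data)
    x$water_roi_vox <- cbind(w %% dm[1], (w %/% dm[1]) %% dm[2],
                             w %/% (dm[1] * dm[2]))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path, grid_dim = NULL, spacing = c(1, 1, 1)) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  seeds <- if (is.data.frame(x$seeds) && nrow(x$seeds))
    seed_set(as.matrix(x$seeds[, c("i", "j", "k")]), x$seeds$role)
  else seed_set(matrix(integer(0), ncol = 3))
  roi <- NULL
  if (!is.null(x$water_roi_vox) && !is.null(grid_dim)) {
    arr <- array(FALSE, dim = grid_dim)
    arr[linear_index(as.matrix(x$water_roi_vox), grid_dim)] <- TRUE
    ref <- ct_volume(array(0, grid_dim), spacing = spacing, check_range = FALSE)
    roi <- voxel_mask(arr, ref, "water_roi")
  }
  mls_session(grade = x$grade, seeds = seeds,
              proximal_slice = x$proximal_slice,
              n_slices = x$n_slices, ct_h2o = x$ct_h2o, water_roi = roi,
              config = load_config(overrides = as.list(x$config)))
}
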