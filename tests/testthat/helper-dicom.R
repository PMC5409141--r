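# Hand-built explicit-VR little-endian DICOM slices for reader tests;
# written byte-by-byte, independent of the package's reader.

dicom_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) {
    pad <- if (vr %in% c("OB", "UN")) as.raw(0) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  hdr <- c(u16(group), u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "OD", "SQ", "UT", "UN"))
    c(hdr, as.raw(c(0, 0)), u32(length(value_raw)), value_raw)
  else c(hdr, u16(length(value_raw)), value_raw)
}

write_test_dicom_slice <- function(path, pixels, z, slope = 1, intercept = -1024,
                                   spacing = c(0.8, 0.9)) {
  # pixels: matrix [col, row] of raw stored values (unsigned 16 bit)
  rows <- ncol(pixels); cols <- nrow(pixels)
  ds <- function(x) charToRaw(paste(format(x, trim = TRUE), collapse = "\\"))
  # DICOM stores row by row (columns fastest); pixels is [col, row], so
  # R's column-major as.vector() already yields that order
  px <- writeBin(as.integer(as.vector(pixels)), raw(), size = 2,
                 endian = "little")
  body <- c(
    dicom_element(0x0018, 0x0050, "DS", ds(1)),
    dicom_element(0x0020, 0x0032, "DS", ds(c(0, 0, z))),
    dicom_element(0x0028, 0x0010, "US",
                  writeBin(as.integer(rows), raw(), size = 2, endian = "little")),
    dicom_element(0x0028, 0x0011, "US",
                  writeBin(as.integer(cols), raw(), size = 2, endian = "little")),
    dicom_element(0x0028, 0x0030, "DS", ds(c(spacing[2], spacing[1]))),
    dicom_element(0x0028, 0x0100, "US",
                  writeBin(16L, raw(), size = 2, endian = "little")),
    dicom_element(0x0028, 0x0103, "US",
                  writeBin(0L, raw(), size = 2, endian = "little")),
    dicom_element(0x0028, 0x1052, "DS", ds(intercept)),
    dicom_element(0x0028, 0x1053, "DS", ds(slope)),
    dicom_element(0x7FE0, 0x0010, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(body, con)
  invisible(path)
}
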