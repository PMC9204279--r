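# Minimal single-frame CT DICOM reader/writer (explicit VR, little
# endian).  Covers exactly what the pipeline needs: stored 16-bit
# grayscale pixels plus the rescale (slope/intercept), spacing and
# identity metadata.  Not a general DICOM implementation.

UID_ROOT <- "1.2.826.0.1.3680043.9.7431"
UID_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

pad_even <- function(x, pad = as.raw(0x20)) {
  if (length(x) %% 2 == 1) c(x, pad) else x
}

uint_le <- function(x, size) {
  r <- raw(size)
  for (i in seq_len(size)) {
    r[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  r
}

dcm_element <- function(group, element, vr, value_raw) {
  long_vr <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  len <- length(value_raw)
  c(uint_le(group, 2), uint_le(element, 2), charToRaw(vr),
    if (long_vr) c(raw(2), uint_le(len, 4)) else uint_le(len, 2),
    value_raw)
}

dcm_str <- function(group, element, vr, s, pad = as.raw(0x20)) {
  dcm_element(group, element, vr, pad_even(charToRaw(s), pad))
}

#' Write a single-frame CT DICOM slice
#'
#' Encodes an HU-valued matrix as unsigned 16-bit stored pixels with
#' RescaleSlope 1 and RescaleIntercept -1024 (stored = HU + 1024), explicit
#' VR little endian.  Instance UIDs are derived from `uid_suffix`, so
#' identical inputs produce byte-identical files.
#'
#' @param hu HU-valued matrix (rows x columns).
#' @param path output file path.
#' @param case_id written as PatientID.
#' @param pixel_spacing length-2 mm per pixel (row, col).
#' @param slice_thickness slice thickness in mm.
#' @param uid_suffix string appended to the package UID root to form the
#'   SOP instance UID; defaults to a digest of the case id.
#' @export
write_dicom_slice <- function(hu, path, case_id = "case",
                              pixel_spacing = c(1, 1), slice_thickness = 3,
                              uid_suffix = NULL) {
  stored <- round(hu) + 1024
  stored[stored < 0] <- 0
  stored[stored > 65535] <- 65535
  if (is.null(uid_suffix))
    uid_suffix <- paste(utf8ToInt(case_id) %% 10, collapse = "")
  inst_uid <- paste0(UID_ROOT, ".", uid_suffix)
  rows <- nrow(stored)
  cols <- ncol(stored)

  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_str(0x0002, 0x0002, "UI", UID_CT_STORAGE, as.raw(0)),
    dcm_str(0x0002, 0x0003, "UI", inst_uid, as.raw(0)),
    dcm_str(0x0002, 0x0010, "UI", UID_EXPLICIT_LE, as.raw(0)),
    dcm_str(0x0002, 0x0012, "UI", paste0(UID_ROOT, ".1"), as.raw(0))
  )
  # row-major pixel order (column index fastest within a row)
  px <- as.integer(t(stored))
  pxraw <- raw(2 * length(px))
  pxraw[c(TRUE, FALSE)] <- as.raw(px %% 256)
  pxraw[c(FALSE, TRUE)] <- as.raw(px %/% 256)

  ds <- c(
    dcm_str(0x0008, 0x0016, "UI", UID_CT_STORAGE, as.raw(0)),
    dcm_str(0x0008, 0x0018, "UI", inst_uid, as.raw(0)),
    dcm_str(0x0008, 0x0060, "CS", "CT"),
    dcm_str(0x0010, 0x0020, "LO", case_id),
    dcm_str(0x0018, 0x0050, "DS", format(slice_thickness)),
    dcm_element(0x0028, 0x0002, "US", uint_le(1, 2)),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", uint_le(rows, 2)),
    dcm_element(0x0028, 0x0011, "US", uint_le(cols, 2)),
    dcm_str(0x0028, 0x0030, "DS",
            paste0(format(pixel_spacing[1]), "\\", format(pixel_spacing[2]))),
    dcm_element(0x0028, 0x0100, "US", uint_le(16, 2)),
    dcm_element(0x0028, 0x0101, "US", uint_le(16, 2)),
    dcm_element(0x0028, 0x0102, "US", uint_le(15, 2)),
    dcm_element(0x0028, 0x0103, "US", uint_le(0, 2)),
    dcm_str(0x0028, 0x1052, "DS", "-1024"),
    dcm_str(0x0028, 0x1053, "DS", "1"),
    dcm_element(0x7FE0, 0x0010, "OW", pxraw)
  )
  out <- c(raw(128), charToRaw("DICM"),
           dcm_element(0x0002, 0x0000, "UL", uint_le(length(meta), 4)),
           meta, ds)
  writeBin(out, path)
  invisible(path)
}

rd_uint <- function(r, off, size) {
  sum(as.integer(r[off + seq_len(size)]) * 256^(seq_len(size) - 1))
}

#' Read a single-frame CT DICOM slice
#'
#' Parses an explicit-VR little-endian single-frame CT file and returns
#' stored pixels plus rescale metadata.  Missing RescaleSlope/Intercept
#' tags default to 1/0 with a warning.
#'
#' @param path DICOM file path.
#' @return Object of class `ct_slice`: `stored_pixels` (rows x cols integer
#'   matrix), `rescale_slope`, `rescale_intercept`, `pixel_spacing`,
#'   `slice_thickness`, `case_id`.
#' @export
read_dicom_slice <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  r <- readBin(path, "raw", file.size(path))
  if (length(r) < 140 || rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  off <- 132L
  while (off + 8 <= length(r)) {
    group <- rd_uint(r, off, 2)
    elem <- rd_uint(r, off + 2, 2)
    vr <- rawToChar(r[off + 5:6])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported or implicit-VR DICOM encoding in ", path)
    if (vr %in% long_vrs) {
      len <- rd_uint(r, off + 8, 4)
      voff <- off + 12L
    } else {
      len <- rd_uint(r, off + 6, 2)
      voff <- off + 8L
    }
    if (voff + len > length(r))
      stop("truncated DICOM file: ", path)
    key <- sprintf("%04X,%04X", group, elem)
    tags[[key]] <- list(vr = vr, value = r[voff + seq_len(len)])
    off <- voff + len
  }
  need <- function(key, what) {
    if (is.null(tags[[key]])) stop("DICOM file lacks ", what, ": ", path)
    tags[[key]]
  }
  as_str <- function(tg) trimws(rawToChar(tg$value[tg$value != as.raw(0)]))
  rows <- rd_uint(need("0028,0010", "Rows")$value, 0, 2)
  cols <- rd_uint(need("0028,0011", "Columns")$value, 0, 2)
  px <- need("7FE0,0010", "PixelData")$value
  if (length(px) != 2 * rows * cols)
    stop("PixelData size mismatch in ", path)
  v <- as.integer(px[c(TRUE, FALSE)]) + 256L * as.integer(px[c(FALSE, TRUE)])
  stored <- t(matrix(v, nrow = cols, ncol = rows))
  if (is.null(tags[["0028,1053"]]) || is.null(tags[["0028,1052"]])) {
    warning("missing rescale tags in ", path, "; defaulting slope=1, intercept=0")
    slope <- 1
    intercept <- 0
  } else {
    slope <- as.numeric(as_str(tags[["0028,1053"]]))
    intercept <- as.numeric(as_str(tags[["0028,1052"]]))
  }
  spacing <- c(1, 1)
  if (!is.null(tags[["0028,0030"]]))
    spacing <- as.numeric(strsplit(as_str(tags[["0028,0030"]]), "\\\\")[[1]])
  thick <- if (!is.null(tags[["0018,0050"]]))
    as.numeric(as_str(tags[["0018,0050"]])) else NA_real_
  case_id <- if (!is.null(tags[["0010,0020"]]))
    as_str(tags[["0010,0020"]]) else basename(path)
  structure(list(stored_pixels = stored, rescale_slope = slope,
                 rescale_intercept = intercept, pixel_spacing = spacing,
                 slice_thickness = thick, case_id = case_id),
            class = "ct_slice")
}

#' Read a CT slice directly in Hounsfield units
#'
#' Convenience wrapper: [read_dicom_slice()] followed by [pixels_to_hu()].
#' @inheritParams read_dicom_slice
#' @return HU-valued numeric matrix with the slice metadata as attributes.
#' @export
read_hu_slice <- function(path) {
  sl <- read_dicom_slice(path)
  hu <- pixels_to_hu(sl$stored_pixels, sl$rescale_slope, sl$rescale_intercept)
  attr(hu, "pixel_spacing") <- sl$pixel_spacing
  attr(hu, "case_id") <- sl$case_id
  hu
}
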