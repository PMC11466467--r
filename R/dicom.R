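# Minimal DICOM CT image storage support: uncompressed, Explicit VR Little
# Endian, single-frame axial CT objects. This covers round-tripping the
# package's own phantom series and reading plain uncompressed CT exports;
# compressed transfer syntaxes, sequences and multi-frame objects are
# rejected rather than guessed at.

DICOM_TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DICOM_CT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.2"
DICOM_IMPL_UID <- "1.2.826.0.1.3680043.10.1457.1"

# -- encoding helpers ---------------------------------------------------------

dcm_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                                   endian = "little")
dcm_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                                   endian = "little")

dcm_pad <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2 == 1) c(bytes, pad) else bytes
}

# One explicit-VR data element.
dcm_element <- function(group, elem, vr, value) {
  body <- switch(vr,
    UI = dcm_pad(charToRaw(value), as.raw(0x00)),
    CS = , LO = , SH = , DS = , IS = dcm_pad(charToRaw(value)),
    US = dcm_uint16(value),
    FD = writeBin(as.numeric(value), raw(), size = 8L, endian = "little"),
    OB = dcm_pad(value, as.raw(0x00)),
    OW = value,
    stopf("unsupported VR '%s' in writer", vr))
  head <- c(dcm_uint16(group), dcm_uint16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW")) {
    c(head, as.raw(c(0, 0)), dcm_uint32(length(body)), body)
  } else {
    if (length(body) > 65534) stopf("element value too long for short VR")
    c(head, dcm_uint16(length(body)), body)
  }
}

dcm_ds <- function(x, digits = 10) {
  paste(formatC(x, format = "g", digits = digits), collapse = "\\")
}

#' Write an image series as single-frame DICOM CT files
#'
#' Emits one uncompressed Explicit-VR-little-endian CT object per slice into
#' `directory` (`slice_0001.dcm`, ...). HU values are stored with the given
#' rescale slope/intercept as signed 16-bit raw values.
#'
#' @param series A [image_series()] object.
#' @param directory Output directory (created if needed).
#' @param slope,intercept Rescale mapping `HU = raw * slope + intercept`.
#' @return `directory`, invisibly.
#' @seealso [read_dicom_series()]
#' @export
write_dicom_series <- function(series, directory, slope = 1,
                               intercept = -1024) {
  stopifnot(inherits(series, "ctiq_series"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  d <- dim(series$voxels)
  raw_vals <- (series$voxels - intercept) / slope
  if (any(abs(raw_vals - round(raw_vals)) > 0.5 + 1e-9)) {
    stopf("HU values not representable with slope %g / intercept %g",
          slope, intercept)
  }
  raw_vals <- round(raw_vals)
  if (any(raw_vals < -32768 | raw_vals > 32767)) {
    stopf("raw values outside int16 range; adjust slope/intercept")
  }
  m <- series$meta
  series_uid <- paste0(DICOM_IMPL_UID, ".", cell_seed(1, m$scanner_id,
                                                      m$recon_label, d[3]))
  study_uid <- paste0(series_uid, ".0")
  desc <- paste(m$protocol_class, m$recon_method, m$recon_label, m$kernel,
                sep = "|")
  for (k in seq_len(d[3])) {
    sop_uid <- paste0(series_uid, ".", k)
    z <- series$slice_positions[k]
    px <- as.integer(t(raw_vals[, , k]))  # DICOM pixel order: row-major
    pixel_bytes <- writeBin(px, raw(), size = 2L, endian = "little")

    ds <- c(
      dcm_element(0x0008, 0x0016, "UI", DICOM_CT_SOP_CLASS),
      dcm_element(0x0008, 0x0018, "UI", sop_uid),
      dcm_element(0x0008, 0x0060, "CS", "CT"),
      dcm_element(0x0008, 0x103E, "LO", desc),
      dcm_element(0x0008, 0x1090, "LO", m$scanner_id),
      dcm_element(0x0018, 0x0050, "DS", dcm_ds(m$slice_thickness)),
      dcm_element(0x0018, 0x0060, "DS", dcm_ds(m$kvp)),
      dcm_element(0x0018, 0x9311, "FD", m$pitch),
      dcm_element(0x0018, 0x9345, "FD", m$ctdi_vol),
      dcm_element(0x0020, 0x000D, "UI", study_uid),
      dcm_element(0x0020, 0x000E, "UI", series_uid),
      dcm_element(0x0020, 0x0013, "IS", as.character(k)),
      dcm_element(0x0020, 0x0032, "DS",
                  dcm_ds(c(0, 0, z))),
      dcm_element(0x0020, 0x0037, "DS", dcm_ds(c(1, 0, 0, 0, 1, 0), 1)),
      dcm_element(0x0020, 0x1041, "DS", dcm_ds(z)),
      dcm_element(0x0028, 0x0002, "US", 1L),
      dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_element(0x0028, 0x0010, "US", d[1]),
      dcm_element(0x0028, 0x0011, "US", d[2]),
      dcm_element(0x0028, 0x0030, "DS", dcm_ds(series$pixel_spacing)),
      dcm_element(0x0028, 0x0100, "US", 16L),
      dcm_element(0x0028, 0x0101, "US", 16L),
      dcm_element(0x0028, 0x0102, "US", 15L),
      dcm_element(0x0028, 0x0103, "US", 1L),
      dcm_element(0x0028, 0x1052, "DS", dcm_ds(intercept)),
      dcm_element(0x0028, 0x1053, "DS", dcm_ds(slope)),
      dcm_element(0x7FE0, 0x0010, "OW", pixel_bytes))

    meta_elems <- c(
      dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      dcm_element(0x0002, 0x0002, "UI", DICOM_CT_SOP_CLASS),
      dcm_element(0x0002, 0x0003, "UI", sop_uid),
      dcm_element(0x0002, 0x0010, "UI", DICOM_TS_EXPLICIT_LE),
      dcm_element(0x0002, 0x0012, "UI", DICOM_IMPL_UID))
    # (0002,0000) group length is UL; encode by hand
    gl <- c(dcm_uint16(0x0002), dcm_uint16(0x0000), charToRaw("UL"),
            dcm_uint16(4L), dcm_uint32(length(meta_elems)))

    con <- file(file.path(directory, sprintf("slice_%04d.dcm", k)), "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(c(gl, meta_elems, ds), con)
    close(con)
  }
  invisible(directory)
}

# -- parsing ------------------------------------------------------------------

dcm_read_uint <- function(bytes, offset, n) {
  sum(as.numeric(bytes[offset + seq_len(n)]) * 256^(seq_len(n) - 1))
}

# Parse a single explicit-VR-LE dataset starting at `offset` (0-based),
# returning a named list keyed "gggg,eeee" with values decoded per VR.
dcm_parse_dataset <- function(bytes, offset) {
  out <- list()
  n <- length(bytes)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (offset + 8 <= n) {
    group <- dcm_read_uint(bytes, offset, 2)
    elem <- dcm_read_uint(bytes, offset + 2, 2)
    vr <- rawToChar(bytes[offset + 5:6])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stopf("not an explicit-VR data element at byte %d (VR '%s')",
            offset, vr)
    }
    if (vr %in% long_vrs) {
      len <- dcm_read_uint(bytes, offset + 8, 4)
      val_off <- offset + 12
    } else {
      len <- dcm_read_uint(bytes, offset + 6, 2)
      val_off <- offset + 8
    }
    if (vr == "SQ") stopf("DICOM sequences are not supported by this reader")
    if (val_off + len > n) stopf("truncated DICOM element at byte %d", offset)
    val_bytes <- bytes[val_off + seq_len(len)]
    key <- sprintf("%04x,%04x", group, elem)
    out[[key]] <- switch(vr,
      UI = , CS = , LO = , SH = , DS = , IS = , PN = , DA = , TM = , ST =
        sub(" +$", "", rawToChar(val_bytes[val_bytes != as.raw(0)])),
      US = dcm_read_uint(val_bytes, 0, 2),
      UL = dcm_read_uint(val_bytes, 0, 4),
      FD = readBin(val_bytes, "double", n = len / 8, size = 8,
                   endian = "little"),
      OW = , OB = val_bytes,
      rawToChar(val_bytes))
    offset <- val_off + len
  }
  out
}

dcm_parse_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM") {
    stopf("%s: not a DICOM part-10 file (missing DICM magic)", path)
  }
  # file meta group: explicit VR; first element (0002,0000) UL group length
  if (dcm_read_uint(bytes, 132, 2) != 2) stopf("%s: missing file meta", path)
  vr <- rawToChar(bytes[132 + 5:6])
  if (vr != "UL") stopf("%s: unexpected file meta structure", path)
  meta_len <- dcm_read_uint(bytes, 132 + 8, 4)
  meta_end <- 132 + 12 + meta_len
  meta <- dcm_parse_dataset(bytes[133:meta_end], 0)
  ts <- meta[["0002,0010"]]
  if (!identical(ts, DICOM_TS_EXPLICIT_LE)) {
    stopf("%s: unsupported transfer syntax '%s' (only Explicit VR LE)",
          path, ts %||% "?")
  }
  dataset <- dcm_parse_dataset(bytes, meta_end)
  dataset
}

dcm_num <- function(ds, key) {
  v <- ds[[key]]
  if (is.null(v)) return(NULL)
  if (is.character(v)) as.numeric(strsplit(v, "\\\\")[[1]]) else as.numeric(v)
}

#' Read a DICOM CT series from a directory
#'
#' Reads every `*.dcm` file in `directory` as an uncompressed Explicit-VR
#' little-endian single-frame CT object, converts raw values to HU through
#' the rescale slope/intercept, and assembles slices sorted by their spatial
#' position (not by file name). Mixed series UIDs, missing rescale tags,
#' non-axial orientation and non-uniform slice spacing are rejected.
#'
#' @param directory Directory containing one CT series.
#' @param spacing_tol Relative tolerance on slice-spacing uniformity.
#' @return A `ctiq_series`.
#' @export
read_dicom_series <- function(directory, spacing_tol = 1e-3) {
  files <- sort(list.files(directory, pattern = "\\.dcm$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0) stopf("no .dcm files in %s", directory)
  parsed <- lapply(files, dcm_parse_file)

  uids <- vapply(parsed, function(d) d[["0020,000e"]] %||% NA_character_,
                 character(1))
  if (length(unique(uids)) != 1) {
    stopf("directory contains %d series (mixed SeriesInstanceUID)",
          length(unique(uids)))
  }
  first <- parsed[[1]]
  rows <- dcm_num(first, "0028,0010"); cols <- dcm_num(first, "0028,0011")
  spacing <- dcm_num(first, "0028,0030")
  if (is.null(rows) || is.null(cols) || is.null(spacing)) {
    stopf("missing Rows/Columns/PixelSpacing")
  }
  orient <- dcm_num(first, "0020,0037")
  if (!is.null(orient) &&
      max(abs(orient - c(1, 0, 0, 0, 1, 0))) > 1e-6) {
    stopf("non-axial (tilted) series are not supported")
  }

  z <- numeric(length(parsed))
  slices <- vector("list", length(parsed))
  for (i in seq_along(parsed)) {
    d <- parsed[[i]]
    slope <- dcm_num(d, "0028,1053"); inter <- dcm_num(d, "0028,1052")
    if (is.null(slope) || is.null(inter)) {
      stopf("%s: missing rescale slope/intercept tags", files[i])
    }
    ipp <- dcm_num(d, "0020,0032")
    z[i] <- if (!is.null(ipp)) ipp[3] else dcm_num(d, "0020,1041") %||% i
    px <- d[["7fe0,0010"]]
    if (is.null(px)) stopf("%s: missing pixel data", files[i])
    signed <- (dcm_num(d, "0028,0103") %||% 1) == 1
    vals <- readBin(px, "integer", n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
    slices[[i]] <- t(matrix(vals, nrow = cols, ncol = rows)) * slope + inter
  }
  ord <- order(z)
  z <- z[ord]; slices <- slices[ord]
  if (length(z) > 2) {
    dz <- diff(z)
    if (max(abs(dz - mean(dz))) > spacing_tol * max(abs(mean(dz)), 1)) {
      stopf("non-uniform slice spacing (max deviation %.3g mm)",
            max(abs(dz - mean(dz))))
    }
  }
  vox <- array(unlist(slices), c(rows, cols, length(slices)))

  desc <- strsplit(first[["0008,103e"]] %||% "body|FBP|FBP|standard",
                   "|", fixed = TRUE)[[1]]
  if (length(desc) < 4) desc <- c(desc, rep("unknown", 4 - length(desc)))
  meta <- acquisition_meta(
    scanner_id = first[["0008,1090"]] %||% "unknown",
    protocol_class = if (desc[1] %in% c("body", "brain")) desc[1] else "body",
    ctdi_vol = dcm_num(first, "0018,9345") %||% 10,
    recon_method = if (desc[2] %in% c("FBP", "IR")) desc[2] else "FBP",
    recon_label = desc[3],
    kvp = dcm_num(first, "0018,0060") %||% 120,
    kernel = desc[4],
    pitch = dcm_num(first, "0018,9311") %||% 1,
    slice_thickness = dcm_num(first, "0018,0050") %||% 1)
  image_series(vox, pixel_spacing = spacing, slice_positions = z, meta = meta)
}
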