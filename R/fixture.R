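# Portable fixture format: `<name>.raw` (int16 little-endian, slice-major)
# plus `<name>.json` (shape, spacing, slice positions, metadata). Bit-exact
# and deterministic, so fixtures can be diffed and versioned as text+raw.

#' Write an image series as a raw + JSON-sidecar fixture
#'
#' HU values are stored as signed 16-bit integers (they must already be
#' integral or within 0.5 HU of an integer and inside \[-32768, 32767\]).
#' Two writes of the same series produce identical bytes.
#'
#' @param series A [image_series()] object.
#' @param path Base path; `.raw` and `.json` extensions are appended (a
#'   trailing `.raw` or `.json` is stripped first).
#' @return The base path, invisibly.
#' @seealso [read_fixture()]
#' @export
write_fixture <- function(series, path) {
  stopifnot(inherits(series, "ctiq_series"))
  base <- sub("\\.(raw|json)$", "", path)
  v <- series$voxels
  if (any(v < -32768 | v > 32767)) {
    stopf("HU values outside int16 range [-32768, 32767]; cannot write fixture")
  }
  iv <- as.integer(round(v))
  con <- file(paste0(base, ".raw"), "wb")
  on.exit(close(con), add = TRUE)
  # slice-major, row-major within slice (column index fastest)
  writeBin(as.integer(aperm(array(iv, dim(v)), c(2L, 1L, 3L))),
           con, size = 2L, endian = "little")
  sidecar <- list(
    format = "ctiq-fixture-v1",
    shape = dim(v),
    pixel_spacing = series$pixel_spacing,
    slice_positions = series$slice_positions,
    meta = unclass(series$meta))
  json <- jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA)
  writeLines(json, paste0(base, ".json"))
  invisible(base)
}

#' Read an image series fixture written by [write_fixture()]
#'
#' @param path Base path (with or without `.raw`/`.json` extension).
#' @return A `ctiq_series`.
#' @export
read_fixture <- function(path) {
  base <- sub("\\.(raw|json)$", "", path)
  json_path <- paste0(base, ".json")
  raw_path <- paste0(base, ".raw")
  if (!file.exists(json_path)) stopf("sidecar not found: %s", json_path)
  if (!file.exists(raw_path)) stopf("raw voxel file not found: %s", raw_path)
  sidecar <- jsonlite::fromJSON(json_path, simplifyVector = TRUE)
  for (key in c("shape", "pixel_spacing", "slice_positions", "meta")) {
    if (is.null(sidecar[[key]])) stopf("sidecar missing required key '%s'", key)
  }
  shape <- as.integer(sidecar$shape)
  n <- prod(shape)
  con <- file(raw_path, "rb")
  on.exit(close(con), add = TRUE)
  iv <- readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                endian = "little")
  if (length(iv) != n) stopf("raw file truncated: expected %d voxels", n)
  # stored row-major within slice: undo the col/row transpose
  vox <- aperm(array(as.numeric(iv), shape[c(2, 1, 3)]), c(2L, 1L, 3L))
  m <- sidecar$meta
  meta <- acquisition_meta(
    scanner_id = m$scanner_id, protocol_class = m$protocol_class,
    ctdi_vol = m$ctdi_vol, recon_method = m$recon_method,
    recon_label = m$recon_label, kvp = m$kvp, kernel = m$kernel,
    pitch = m$pitch, slice_thickness = m$slice_thickness)
  image_series(vox, pixel_spacing = as.numeric(sidecar$pixel_spacing),
               slice_positions = as.numeric(sidecar$slice_positions),
               meta = meta)
}
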