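# Internal image model: an image series is a stack of axial HU slices with
# physical pixel spacing and acquisition metadata. All downstream modules
# (NPS, contrast, TTF, detectability) consume this one container.

#' Acquisition metadata for a CT image series
#'
#' Captures the protocol information the harmonization procedure keys on:
#' which scanner produced the series, the protocol class (body or brain,
#' which determines the reference phantom geometry), the delivered dose
#' (CTDI_vol, mGy) and the reconstruction method and strength label.
#'
#' @param scanner_id Free-text scanner identifier.
#' @param protocol_class `"body"` or `"brain"`.
#' @param ctdi_vol Volume CT dose index in mGy; must be positive.
#' @param recon_method `"FBP"` or `"IR"`.
#' @param recon_label Free-text reconstruction label, e.g. `"FBP"` or
#'   `"hybrid-3"`.
#' @param kvp Tube potential in kV.
#' @param kernel Reconstruction kernel name.
#' @param pitch Helical pitch (dimensionless).
#' @param slice_thickness Slice thickness in mm; must be positive.
#' @return An object of class `ctiq_meta` (a named list).
#' @examples
#' acquisition_meta("scannerA", "body", ctdi_vol = 15)
#' @export
acquisition_meta <- function(scanner_id = "unknown",
                             protocol_class = c("body", "brain"),
                             ctdi_vol = 10,
                             recon_method = c("FBP", "IR"),
                             recon_label = "FBP",
                             kvp = 120,
                             kernel = "standard",
                             pitch = 0.8,
                             slice_thickness = 2) {
  protocol_class <- match.arg(protocol_class)
  recon_method <- match.arg(recon_method)
  if (!is.numeric(ctdi_vol) || length(ctdi_vol) != 1 || !is.finite(ctdi_vol) ||
      ctdi_vol <= 0) {
    stopf("ctdi_vol must be a single positive number (mGy), got %s",
          paste(ctdi_vol, collapse = ","))
  }
  if (!is.numeric(slice_thickness) || slice_thickness <= 0) {
    stopf("slice_thickness must be positive (mm)")
  }
  structure(
    list(scanner_id = as.character(scanner_id),
         protocol_class = protocol_class,
         ctdi_vol = as.numeric(ctdi_vol),
         recon_method = recon_method,
         recon_label = as.character(recon_label),
         kvp = as.numeric(kvp),
         kernel = as.character(kernel),
         pitch = as.numeric(pitch),
         slice_thickness = as.numeric(slice_thickness)),
    class = "ctiq_meta")
}

#' Construct a CT image series
#'
#' The universal input of the package: a 3D stack of Hounsfield-unit values
#' with physical pixel spacing. Voxels are stored as an array indexed
#' `[row, col, slice]`; physical in-plane coordinates are taken relative to
#' the image centre, so `x = (col - (ncol+1)/2) * spacing_col`.
#'
#' @param voxels Numeric 3D array `[row, col, slice]` of HU values, or a
#'   matrix for a single slice.
#' @param pixel_spacing Length-2 numeric, mm per pixel along (row, col).
#' @param slice_positions Numeric vector of slice positions in mm, strictly
#'   monotone; defaults to `slice_thickness`-spaced positions from 0.
#' @param meta An [acquisition_meta()] object.
#' @return An object of class `ctiq_series`.
#' @examples
#' s <- image_series(array(0, c(32, 32, 2)), pixel_spacing = c(1, 1))
#' dim(s$voxels)
#' @export
image_series <- function(voxels, pixel_spacing = c(1, 1),
                         slice_positions = NULL,
                         meta = acquisition_meta()) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    stopf("voxels must be a [row, col, slice] array")
  }
  if (!all(is.finite(voxels))) stopf("voxels must be finite HU values")
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1) pixel_spacing <- rep(pixel_spacing, 2)
  if (length(pixel_spacing) != 2 || any(pixel_spacing <= 0)) {
    stopf("pixel_spacing must be two positive values (mm)")
  }
  n_slice <- dim(voxels)[3]
  if (is.null(slice_positions)) {
    slice_positions <- seq(0, by = meta$slice_thickness, length.out = n_slice)
  }
  slice_positions <- as.numeric(slice_positions)
  if (length(slice_positions) != n_slice) {
    stopf("slice_positions length (%d) must match slice count (%d)",
          length(slice_positions), n_slice)
  }
  if (n_slice > 1 && !(all(diff(slice_positions) > 0) ||
                       all(diff(slice_positions) < 0))) {
    stopf("slice_positions must be strictly monotone")
  }
  if (!inherits(meta, "ctiq_meta")) stopf("meta must be an acquisition_meta()")
  structure(
    list(voxels = voxels,
         pixel_spacing = pixel_spacing,
         slice_positions = slice_positions,
         meta = meta),
    class = "ctiq_series")
}

#' @export
print.ctiq_series <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ctiq_series> %d x %d x %d slices, spacing %.3f x %.3f mm\n",
              d[1], d[2], d[3], x$pixel_spacing[1], x$pixel_spacing[2]))
  cat(sprintf("  scanner %s | %s | CTDI_vol %.1f mGy | %s (%s)\n",
              x$meta$scanner_id, x$meta$protocol_class, x$meta$ctdi_vol,
              x$meta$recon_method, x$meta$recon_label))
  invisible(x)
}

#' @export
print.ctiq_meta <- function(x, ...) {
  cat(sprintf("<ctiq_meta> %s | %s | %.1f mGy | %s (%s) | %g kVp | %s\n",
              x$scanner_id, x$protocol_class, x$ctdi_vol, x$recon_method,
              x$recon_label, x$kvp, x$kernel))
  invisible(x)
}

#' @keywords internal
#' @noRd
series_shape <- function(series) dim(series$voxels)

#' Physical in-plane coordinates of pixel centres
#'
#' @param series a `ctiq_series` (or anything with voxel dims + spacing).
#' @return list with `x` (per column, mm) and `y` (per row, mm) relative to
#'   the image centre.
#' @keywords internal
#' @noRd
pixel_coords <- function(n_row, n_col, spacing) {
  list(y = (seq_len(n_row) - (n_row + 1) / 2) * spacing[1],
       x = (seq_len(n_col) - (n_col + 1) / 2) * spacing[2])
}
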