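# Insert contrast and contrast-to-noise ratio on the sensitometry module.
# Contrast is the HU difference between an insert and the surrounding
# background; CNR divides that contrast by the background noise SD. Both
# are measured on the composite (slice-averaged) image of the module.

#' Composite (slice-averaged) image of a series
#'
#' @param series A `ctiq_series`.
#' @param slice_range Integer vector of slice indices (default: all).
#' @return Numeric matrix of HU values with attribute `pixel_spacing`.
#' @export
composite_image <- function(series, slice_range = NULL) {
  stopifnot(inherits(series, "ctiq_series"))
  d <- dim(series$voxels)
  slice_range <- slice_range %||% seq_len(d[3])
  if (!length(slice_range)) stopf("slice_range is empty")
  if (any(slice_range < 1 | slice_range > d[3])) {
    stopf("slice_range outside 1..%d", d[3])
  }
  img <- rowMeans(series$voxels[, , slice_range, drop = FALSE], dims = 2)
  attr(img, "pixel_spacing") <- series$pixel_spacing
  img
}

#' @keywords internal
#' @noRd
disk_mask <- function(shape, spacing, center, radius_lo, radius_hi) {
  co <- pixel_coords(shape[1], shape[2], spacing)
  r2 <- outer((co$y - center[2])^2, (co$x - center[1])^2, "+")
  r2 >= radius_lo^2 & r2 <= radius_hi^2
}

#' Measure insert contrast and CNR on a composite image
#'
#' For each insert, the insert mean is taken over a concentric disk of
#' `erode * diameter` (eroded to stay clear of edge blur); the background
#' mean and SD are taken over an annulus around the insert from
#' `radius + bg_margin` to `radius + bg_margin + bg_width`. Contrast is
#' `mean_insert - mean_bg` and CNR is `contrast / sd_bg`. The annulus must
#' not intersect any other insert.
#'
#' @param composite Matrix from [composite_image()] (or a `ctiq_series`,
#'   whose composite is taken), with `pixel_spacing` attribute.
#' @param inserts List of [insert_spec()] (or a single one).
#' @param bg_margin Gap between insert edge and annulus, mm.
#' @param bg_width Annulus radial width, mm.
#' @param erode Inner-disk erosion factor applied to the diameter.
#' @param pixel_spacing Override spacing if `composite` lacks the attribute.
#' @return Data frame with one row per insert: `label`, `contrast` (HU),
#'   `cnr`, `mean_insert`, `mean_bg`, `sd_bg`.
#' @export
contrast_cnr <- function(composite, inserts, bg_margin = 2, bg_width = 4,
                         erode = 0.7, pixel_spacing = NULL) {
  if (inherits(composite, "ctiq_series")) composite <- composite_image(composite)
  spacing <- pixel_spacing %||% attr(composite, "pixel_spacing")
  if (is.null(spacing)) stopf("pixel_spacing unknown; pass it explicitly")
  spacing <- rep(as.numeric(spacing), length.out = 2)
  if (inherits(inserts, "ctiq_insert")) inserts <- list(inserts)
  shape <- dim(composite)

  rows <- lapply(inserts, function(ins) {
    rad <- ins$diameter / 2
    inner <- disk_mask(shape, spacing, ins$center, 0, erode * rad)
    lo <- rad + bg_margin
    hi <- lo + bg_width
    ann <- disk_mask(shape, spacing, ins$center, lo, hi)
    if (!any(inner)) stopf("insert '%s' covers no pixels", ins$label)
    if (!any(ann)) stopf("background annulus for '%s' covers no pixels",
                         ins$label)
    for (other in inserts) {
      gap <- sqrt(sum((other$center - ins$center)^2))
      touches <- if (identical(other, ins)) FALSE
      else gap - other$diameter / 2 < hi && gap + other$diameter / 2 > lo
      if (touches) {
        stopf("background annulus of '%s' intersects insert '%s'",
              ins$label, other$label)
      }
    }
    mean_insert <- mean(composite[inner])
    mean_bg <- mean(composite[ann])
    sd_bg <- stats::sd(composite[ann])
    if (!is.finite(sd_bg) || sd_bg <= 0) {
      sd_bg <- NA_real_
    }
    data.frame(label = ins$label,
               contrast = mean_insert - mean_bg,
               cnr = (mean_insert - mean_bg) / sd_bg,
               mean_insert = mean_insert, mean_bg = mean_bg, sd_bg = sd_bg,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize contrast and CNR across acquisitions
#'
#' Aggregates per-insert contrast/CNR over all dose and reconstruction
#' combinations within each group (typically scanner x protocol), the shape
#' in which sensitometry results are reported: per insert, mean and SD of
#' contrast and of CNR across acquisitions.
#'
#' @param results Data frame: rbind of [contrast_cnr()] outputs with added
#'   grouping columns.
#' @param group_cols Character vector of grouping column names.
#' @return Data frame with `label`, group columns, `n`, `contrast_mean`,
#'   `contrast_sd`, `cnr_mean`, `cnr_sd`.
#' @export
summarize_contrast <- function(results, group_cols = character(0)) {
  if (!nrow(results)) stopf("empty result set")
  key <- interaction(results[c("label", group_cols)], drop = TRUE)
  parts <- split(results, key)
  out <- lapply(parts, function(g) {
    cbind(g[1, c("label", group_cols), drop = FALSE],
          data.frame(n = nrow(g),
                     contrast_mean = mean(g$contrast),
                     contrast_sd = if (nrow(g) > 1) stats::sd(g$contrast) else 0,
                     cnr_mean = mean(g$cnr),
                     cnr_sd = if (nrow(g) > 1) stats::sd(g$cnr) else 0))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
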