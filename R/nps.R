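# Noise power spectrum estimation. The 2D NPS of a uniform region is the
# ROI-averaged squared magnitude of the 2D DFT of detrended patches,
#   NPS2D(fx, fy) = (dx dy)/(Nx Ny) * mean_i |FFT2D(I_i - P_i)|^2,
# where P_i is the per-ROI least-squares 2nd-order polynomial surface. The
# radial rebinning and the scalar noise/texture metrics (noise SD, NPS
# peak magnitude and location, weighted mean frequency, area under the
# radial curve) summarize noise magnitude and texture.

#' ROI sampling plan for NPS estimation
#'
#' Square ROIs are tiled (with overlap allowed) over a centred square
#' region of the uniform module, on every slice. The default — 64 x 64
#' pixel ROIs with 50% overlap over the central half of the image — is the
#' common practice for uniform-module NPS work.
#'
#' @param roi_size ROI side in pixels (>= 16).
#' @param stride Step between ROI origins in pixels (>= roi_size / 2).
#' @param region_frac Side of the centred sampling region as a fraction of
#'   the smaller image dimension.
#' @return Object of class `ctiq_roigrid`.
#' @export
roi_grid <- function(roi_size = 64, stride = roi_size / 2,
                     region_frac = 0.5) {
  if (roi_size < 16) stopf("roi_size must be >= 16 pixels")
  if (stride < roi_size / 2) stopf("stride must be >= roi_size / 2")
  stopifnot(region_frac > 0, region_frac <= 1)
  structure(list(roi_size = as.integer(roi_size), stride = as.integer(stride),
                 region_frac = region_frac),
            class = "ctiq_roigrid")
}

#' @keywords internal
#' @noRd
roi_origins <- function(n, roi_size, stride, region_frac) {
  side <- floor(n * region_frac)
  lo <- floor((n - side) / 2) + 1L
  if (side < roi_size) return(integer(0))
  seq(lo, lo + side - roi_size, by = stride)
}

# Precomputed orthonormal basis of 2D polynomials up to order 2 on a
# roi_size^2 grid; detrending is projection onto its complement.
#' @keywords internal
#' @noRd
poly2_basis <- function(n) {
  x <- rep(seq_len(n) - (n + 1) / 2, times = n)
  y <- rep(seq_len(n) - (n + 1) / 2, each = n)
  X <- cbind(1, x, y, x * y, x^2, y^2)
  qr.Q(qr(X))
}

#' Estimate the 2D noise power spectrum of a uniform series
#'
#' @param series A `ctiq_series` whose sampled region is uniform (e.g. the
#'   uniformity module or a water phantom).
#' @param grid A [roi_grid()].
#' @return Object of class `ctiq_nps2d`: DC-centred `fx`, `fy` (1/mm),
#'   matrix `values` (HU^2 mm^2), `n_roi`, `pixel_spacing`, plus the
#'   per-ROI detrended variances (`roi_var`) and SDs (`roi_sd`) used for
#'   Parseval checks and the noise-SD metric.
#' @export
compute_nps2d <- function(series, grid = roi_grid()) {
  stopifnot(inherits(series, "ctiq_series"), inherits(grid, "ctiq_roigrid"))
  d <- dim(series$voxels)
  rs <- grid$roi_size
  orow <- roi_origins(d[1], rs, grid$stride, grid$region_frac)
  ocol <- roi_origins(d[2], rs, grid$stride, grid$region_frac)
  if (!length(orow) || !length(ocol)) {
    stopf("ROI grid (size %d) exceeds the %d x %d sampling region",
          rs, floor(d[1] * grid$region_frac), floor(d[2] * grid$region_frac))
  }
  n_roi <- length(orow) * length(ocol) * d[3]
  if (n_roi < 2) stopf("need at least 2 ROIs, grid yields %d", n_roi)

  Q <- poly2_basis(rs)
  acc <- matrix(0, rs, rs)
  roi_var <- numeric(n_roi)
  i <- 0L
  for (k in seq_len(d[3])) {
    sl <- series$voxels[, , k]
    for (r0 in orow) {
      for (c0 in ocol) {
        patch <- sl[r0:(r0 + rs - 1), c0:(c0 + rs - 1)]
        v <- as.vector(patch)
        resid <- v - Q %*% crossprod(Q, v)
        i <- i + 1L
        roi_var[i] <- mean(resid^2)
        acc <- acc + Mod(fft(matrix(resid, rs, rs)))^2
      }
    }
  }
  dx <- series$pixel_spacing[2]; dy <- series$pixel_spacing[1]
  values <- fft_shift(acc / n_roi) * dx * dy / (rs * rs)
  structure(list(
    fx = fft_shift(fft_freq(rs, dx)),
    fy = fft_shift(fft_freq(rs, dy)),
    values = values,
    n_roi = n_roi,
    pixel_spacing = series$pixel_spacing,
    roi_var = roi_var,
    roi_sd = sqrt(roi_var * rs * rs / (rs * rs - 6))),
    class = "ctiq_nps2d")
}

#' Rebin a 2D NPS onto a radial-frequency curve
#'
#' Values are averaged in annular bins of `bin_width` centred at
#' `k * bin_width`; the DC bin (`rho < bin_width / 2`) is excluded and bins
#' run up to the (smaller-axis) Nyquist frequency. Empty bins are dropped.
#'
#' @param nps2d A [compute_nps2d()] result (or compatible list).
#' @param bin_width Radial bin width in 1/mm; default one FFT cell.
#' @return Object of class `ctiq_nps1d` with `rho`, `values`, `bin_width`,
#'   `counts`.
#' @export
radial_nps <- function(nps2d, bin_width = NULL) {
  if (is.null(bin_width)) {
    bin_width <- min(diff(nps2d$fx)[1], diff(nps2d$fy)[1])
  }
  if (bin_width <= 0) stopf("bin_width must be positive")
  rho <- sqrt(outer(nps2d$fy^2, nps2d$fx^2, "+"))
  nyq <- min(max(abs(nps2d$fx)), max(abs(nps2d$fy)),
             1 / (2 * max(nps2d$pixel_spacing)))
  bin <- round(rho / bin_width)
  keep <- bin >= 1 & rho <= nyq + bin_width / 2
  if (!any(keep)) {
    # bin wider than the whole band: one bin holding all non-DC cells
    nz <- rho > 0
    return(structure(list(rho = mean(rho[nz]),
                          values = mean(nps2d$values[nz]),
                          counts = sum(nz), bin_width = bin_width),
                     class = "ctiq_nps1d"))
  }
  sums <- tapply(nps2d$values[keep], bin[keep], mean)
  counts <- tapply(nps2d$values[keep], bin[keep], length)
  centers <- as.numeric(names(sums)) * bin_width
  ord <- order(centers)
  structure(list(rho = centers[ord], values = as.numeric(sums)[ord],
                 counts = as.numeric(counts)[ord], bin_width = bin_width),
            class = "ctiq_nps1d")
}

#' @keywords internal
#' @noRd
moving_average3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  c(mean(x[1:2]), (x[-c(1, 2)] + x[-c(1, n)] + x[-c(n - 1, n)]) / 3,
    mean(x[(n - 1):n]))
}

#' Scalar noise and texture metrics from the NPS
#'
#' Computes, from a uniform series:
#' * `noise_sd` — RMS of the per-ROI detrended SDs (HU);
#' * `nps_p` — peak magnitude of the radial NPS (HU^2 mm^2);
#' * `freq_p` — frequency of that peak (1/mm; lowest frequency on ties);
#' * `freq_m` — NPS-weighted mean frequency (1/mm);
#' * `auc_nps` — trapezoidal area under the radial curve (HU^2 mm).
#'
#' Peak statistics are read from a 3-bin moving-average-smoothed copy of
#' the radial curve (single-periodogram-bin spikes are unstable); `freq_m`
#' and `auc_nps` use the raw curve, which is retained in the result.
#'
#' @param series A uniform `ctiq_series`.
#' @param grid A [roi_grid()].
#' @param bin_width Radial bin width in 1/mm (default one FFT cell).
#' @param smooth_peak Use the smoothed curve for `nps_p`/`freq_p`.
#' @return Object of class `ctiq_noisemetrics`; the underlying `nps2d` and
#'   `nps1d` objects are attached.
#' @export
noise_metrics <- function(series, grid = roi_grid(), bin_width = NULL,
                          smooth_peak = TRUE) {
  n2 <- compute_nps2d(series, grid)
  n1 <- radial_nps(n2, bin_width)
  curve <- if (smooth_peak) moving_average3(n1$values) else n1$values
  ipk <- which(curve == max(curve))[1]
  total <- sum(n1$values)
  structure(list(
    noise_sd = sqrt(mean(n2$roi_sd^2)),
    nps_p = curve[ipk],
    freq_p = n1$rho[ipk],
    freq_m = if (total > 0) sum(n1$rho * n1$values) / total else 0,
    auc_nps = trapz_area(n1$rho, n1$values),
    nps2d = n2, nps1d = n1),
    class = "ctiq_noisemetrics")
}

#' @export
print.ctiq_noisemetrics <- function(x, ...) {
  cat(sprintf(paste0("<ctiq_noisemetrics> noise %.2f HU | NPS_p %.1f ",
                     "HU^2mm^2 @ %.2f /mm | FREQ_m %.3f /mm | AUC %.1f\n"),
              x$noise_sd, x$nps_p, x$freq_p, x$freq_m, x$auc_nps))
  invisible(x)
}
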