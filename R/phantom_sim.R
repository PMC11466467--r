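# Synthetic phantom generator. Produces HU image series with a known,
# controllable radial noise power spectrum, noise magnitude scaling as
# 1/sqrt(CTDI_vol), a parametric iterative-reconstruction (IR) emulation
# (noise suppression plus a spectral shift toward low frequency), and
# cylindrical inserts with anti-aliased edges for contrast/TTF/detectability
# work. Everything is seeded and reproducible; the planted parameters are
# the ground truth the estimators are validated against.

#' Radial noise-spectrum model
#'
#' The noise power spectrum of the simulated reconstruction follows the
#' ramp-like shape \eqn{g(\rho) = A \rho \exp(-(\rho/\rho_c)^p)}: zero at DC,
#' rising roughly linearly (as an FBP ramp filter does), and rolling off
#' beyond a corner frequency set by the reconstruction kernel. The absolute
#' amplitude is irrelevant — series are scaled to `target_sd` at the
#' reference dose — only the shape matters.
#'
#' @param corner_freq Corner frequency \eqn{\rho_c} in 1/mm. The spectrum
#'   peaks at `corner_freq * (1/sharpness)^(1/sharpness)`.
#' @param sharpness Roll-off exponent p (dimensionless).
#' @param target_sd Noise SD in HU produced at the reference CTDI_vol for a
#'   scanner of efficiency 1.
#' @param amplitude Shape amplitude A (HU^2 mm^2); kept for completeness.
#' @return Object of class `ctiq_nsm` with an `eval(rho)` closure.
#' @export
noise_spectrum_model <- function(corner_freq = 0.35, sharpness = 2,
                                 target_sd = 10, amplitude = 1) {
  stopifnot(corner_freq > 0, sharpness > 0, target_sd > 0, amplitude > 0)
  obj <- list(corner_freq = corner_freq, sharpness = sharpness,
              target_sd = target_sd, amplitude = amplitude)
  obj$eval <- function(rho) {
    amplitude * rho * exp(-(rho / corner_freq)^sharpness)
  }
  structure(obj, class = "ctiq_nsm")
}

#' Virtual scanner profile
#'
#' `efficiency` is the dose efficiency relative to the reference scanner:
#' at equal CTDI_vol, noise variance scales as `1/efficiency`, so a scanner
#' with efficiency `1/1.15` needs 15% more dose to reach the reference
#' noise level.
#'
#' @param name Scanner label.
#' @param efficiency Positive dose-efficiency factor.
#' @param body_spectrum,brain_spectrum [noise_spectrum_model()] per protocol
#'   class.
#' @return Object of class `ctiq_scanner`.
#' @export
scanner_profile <- function(name = "scanner",
                            efficiency = 1,
                            body_spectrum = noise_spectrum_model(
                              corner_freq = 0.35, target_sd = 10),
                            brain_spectrum = noise_spectrum_model(
                              corner_freq = 0.30, target_sd = 5)) {
  stopifnot(is.numeric(efficiency), efficiency > 0)
  structure(list(name = name, efficiency = efficiency,
                 body_spectrum = body_spectrum,
                 brain_spectrum = brain_spectrum),
            class = "ctiq_scanner")
}

#' @keywords internal
#' @noRd
profile_spectrum <- function(profile, protocol_class) {
  switch(protocol_class, body = profile$body_spectrum,
         brain = profile$brain_spectrum)
}

#' Parametric iterative-reconstruction emulation
#'
#' IR is emulated as a frequency-domain operator on the noise component:
#' \eqn{H_L(\rho) = (1-\alpha) + \alpha \exp(-(\rho/f_L)^2)}. `alpha` in
#' \[0,1\] is the noise-suppression weight and `f_L` the low-pass corner
#' (1/mm); larger `alpha` and smaller `f_L` reduce noise more and shift the
#' NPS toward low frequency, mimicking what strong hybrid and model-based
#' IR do to noise texture. Level 0 is the identity (FBP).
#'
#' If `alpha`/`f_l` are not given they follow the family defaults:
#' `"hybrid"` gives `alpha = 0.12 * level`, `f_l = 0.30`; `"model-based"`
#' gives `alpha = min(0.70 + 0.09 * level, 0.98)`, `f_l = 0.10`.
#'
#' @param family Free-text IR family (`"hybrid"`, `"model-based"`, ...).
#' @param level Integer strength level >= 0; 0 means identity/FBP.
#' @param alpha Noise-suppression weight in \[0,1\]; default from family.
#' @param f_l Low-pass corner frequency in 1/mm; default from family.
#' @return Object of class `ctiq_ir`.
#' @export
ir_emulation <- function(family = "hybrid", level = 1, alpha = NULL,
                         f_l = NULL) {
  stopifnot(level >= 0)
  if (is.null(alpha)) {
    alpha <- if (level == 0) 0
    else if (family == "model-based") min(0.70 + 0.09 * level, 0.98)
    else min(0.12 * level, 0.95)
  }
  if (is.null(f_l)) {
    f_l <- if (family == "model-based") 0.10 else 0.30
  }
  if (alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1], got %g", alpha)
  stopifnot(f_l > 0)
  if (level == 0) alpha <- 0
  structure(list(family = family, level = as.integer(level),
                 alpha = alpha, f_l = f_l,
                 label = if (level == 0) "FBP"
                         else paste0(family, "-", level)),
            class = "ctiq_ir")
}

#' Cylindrical insert specification
#'
#' @param center Length-2 numeric (x, y) in mm relative to the image centre.
#' @param diameter Insert diameter in mm (> 0).
#' @param delta_hu Contrast versus background in HU.
#' @param label Insert name.
#' @return Object of class `ctiq_insert`.
#' @export
insert_spec <- function(center = c(0, 0), diameter, delta_hu,
                        label = "insert") {
  stopifnot(length(center) == 2, diameter > 0)
  structure(list(center = as.numeric(center), diameter = as.numeric(diameter),
                 delta_hu = as.numeric(delta_hu), label = label),
            class = "ctiq_insert")
}

#' Insert layouts of the modular image-quality phantom
#'
#' Returns the insert list for each simulated phantom module:
#' * `uniformity` — no inserts (NPS module);
#' * `sensitometry` — seven material rods (12 mm) equally spaced on a circle
#'   of radius `0.25 * fov`, with default body-protocol contrasts
#'   Polystyrene -128, Acrylic 25, LDPE -183, Derlin 245, PMP -270,
#'   Air -1055, Teflon 814 HU;
#' * `low_contrast` — one 7 mm disk of 10 HU contrast at the centre;
#' * `edge_disk` — one 12 mm disk of 25 HU contrast at the centre (the
#'   circular-edge TTF target).
#'
#' @param module One of `"uniformity"`, `"sensitometry"`, `"low_contrast"`,
#'   `"edge_disk"`.
#' @param fov Field of view in mm.
#' @param delta_hu Optional named numeric vector overriding the sensitometry
#'   contrasts (e.g. per protocol class).
#' @return List of [insert_spec()] objects (empty for `uniformity`).
#' @export
catphan_layout <- function(module = c("uniformity", "sensitometry",
                                      "low_contrast", "edge_disk"),
                           fov = 256, delta_hu = NULL) {
  module <- match.arg(module)
  if (module == "uniformity") return(list())
  # sub-pixel centre offsets: a grid-aligned centre makes the exact radial
  # distances degenerate and starves the oversampled ESF bins
  if (module == "low_contrast") {
    return(list(insert_spec(c(0.23, 0.41), diameter = 7, delta_hu = 10,
                            label = "low_contrast_7mm")))
  }
  if (module == "edge_disk") {
    return(list(insert_spec(c(0.31, -0.22), diameter = 12, delta_hu = 25,
                            label = "edge_disk_12mm")))
  }
  materials <- c(Polystyrene = -128, Acrylic = 25, LDPE = -183,
                 Derlin = 245, PMP = -270, Air = -1055, Teflon = 814)
  if (!is.null(delta_hu)) materials[names(delta_hu)] <- delta_hu
  r <- 0.25 * fov
  diameter <- 12
  if (r + diameter / 2 >= fov / 2) stopf("fov %g mm too small for layout", fov)
  angles <- pi / 2 + 2 * pi * (seq_along(materials) - 1) / length(materials)
  mapply(function(mat, dhu, a) {
    insert_spec(center = r * c(cos(a), sin(a)), diameter = diameter,
                delta_hu = dhu, label = mat)
  }, names(materials), materials, angles, SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Render a noiseless insert image
#'
#' Inserts are drawn with area-weighted anti-aliased edges (subpixel
#' supersampling) on a zero-HU background, then optionally blurred by a
#' Gaussian system PSF of SD `blur_sigma` (mm) applied in the frequency
#' domain. The blur gives the simulated scanner a finite, known resolution:
#' its true task transfer function is exactly
#' \eqn{\exp(-2\pi^2\sigma_b^2\rho^2)}.
#'
#' @param shape Length-2 integer (rows, cols).
#' @param spacing Length-2 numeric pixel size in mm.
#' @param inserts List of [insert_spec()].
#' @param blur_sigma Gaussian PSF SD in mm (0 disables).
#' @param supersample Subpixel sampling factor per axis.
#' @return Numeric matrix of HU values.
#' @export
render_inserts <- function(shape, spacing, inserts, blur_sigma = 0.6,
                           supersample = 8) {
  img <- matrix(0, shape[1], shape[2])
  co <- pixel_coords(shape[1], shape[2], spacing)
  half <- max(spacing) / 2
  off <- (seq_len(supersample) - (supersample + 1) / 2) / supersample
  for (ins in inserts) {
    rad <- ins$diameter / 2
    if (max(abs(ins$center)) + rad > min(shape * spacing) / 2) {
      stopf("insert '%s' extends outside the field of view", ins$label)
    }
    rows <- which(abs(co$y - ins$center[2]) <= rad + 2 * half)
    cols <- which(abs(co$x - ins$center[1]) <= rad + 2 * half)
    if (!length(rows) || !length(cols)) next
    sub_y <- as.vector(outer(off * spacing[1], co$y[rows], "+")) - ins$center[2]
    sub_x <- as.vector(outer(off * spacing[2], co$x[cols], "+")) - ins$center[1]
    # coverage[row, col] = fraction of subpixels inside the circle
    d2 <- outer(sub_y^2, sub_x^2, "+")
    inside <- matrix(as.numeric(d2 <= rad^2),
                     nrow = supersample * length(rows))
    cov <- matrix(0, length(rows), length(cols))
    for (j in seq_along(cols)) {
      block <- inside[, (j - 1) * supersample + seq_len(supersample),
                      drop = FALSE]
      cov[, j] <- rowsum(rowSums(block),
                         rep(seq_along(rows), each = supersample)) /
        supersample^2
    }
    img[rows, cols] <- img[rows, cols] + ins$delta_hu * cov
  }
  if (blur_sigma > 0) {
    rho2 <- radial_freq_grid(shape[1], shape[2], spacing)^2
    img <- Re(fft(fft(img) * exp(-2 * pi^2 * blur_sigma^2 * rho2),
                  inverse = TRUE)) / length(img)
  }
  img
}

#' Generate a stationary correlated-noise series
#'
#' White Gaussian noise is filtered in the frequency domain by the square
#' root of the radialized spectrum model, which makes the expected NPS of
#' the output exactly the model shape. The spatial SD is set to
#' `model$target_sd * sqrt(ctdi_ref / ctdi) / sqrt(efficiency)`, i.e. noise
#' variance proportional to `1 / (efficiency * CTDI_vol)`, the standard
#' quantum-noise dose law.
#'
#' @param model A [noise_spectrum_model()].
#' @param ctdi,ctdi_ref Acquisition and reference CTDI_vol in mGy (> 0).
#' @param efficiency Scanner dose efficiency (see [scanner_profile()]).
#' @param shape Length-2 integer (rows, cols).
#' @param spacing Pixel size in mm (scalar or length 2).
#' @param n_slices Number of slices.
#' @param seed Integer RNG seed (required: series are reproducible).
#' @param meta Optional [acquisition_meta()] attached to the series.
#' @return A `ctiq_series` of pure zero-mean noise.
#' @export
synth_noise_series <- function(model, ctdi, ctdi_ref = ctdi, efficiency = 1,
                               shape = c(256, 256), spacing = 1,
                               n_slices = 16, seed,
                               meta = NULL) {
  if (ctdi <= 0 || ctdi_ref <= 0) stopf("CTDI_vol must be positive")
  stopifnot(efficiency > 0, n_slices >= 1)
  if (missing(seed)) stopf("seed is required for reproducible synthesis")
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  sd_target <- model$target_sd * sqrt(ctdi_ref / ctdi) / sqrt(efficiency)
  rho <- radial_freq_grid(shape[1], shape[2], spacing)
  h <- sqrt(model$eval(rho))
  scale <- sd_target / sqrt(mean(h^2))
  set.seed(seed)
  vox <- array(0, c(shape[1], shape[2], n_slices))
  npx <- prod(shape)
  for (k in seq_len(n_slices)) {
    w <- matrix(stats::rnorm(npx), shape[1], shape[2])
    vox[, , k] <- Re(fft(fft(w) * h, inverse = TRUE)) / npx * scale
  }
  if (is.null(meta)) meta <- acquisition_meta(ctdi_vol = ctdi)
  image_series(vox, pixel_spacing = spacing, meta = meta)
}

#' Apply the parametric IR operator to the noise component of a series
#'
#' Filters `series - signal` slice-wise in the frequency domain by
#' \eqn{H_L(\rho) = (1-\alpha)+\alpha\exp(-(\rho/f_L)^2)} and adds the
#' signal back. Since \eqn{H_L \le 1} noise never increases; level 0
#' returns the input unchanged. The deterministic signal (inserts) is left
#' untouched, matching an emulation in which IR acts on noise magnitude and
#' texture.
#'
#' @param series A `ctiq_series`.
#' @param ir An [ir_emulation()].
#' @param signal Optional noiseless signal: a matrix (applied to every
#'   slice) or array matching the series; defaults to zero (pure noise).
#' @return A `ctiq_series` with updated recon metadata.
#' @export
emulate_ir <- function(series, ir, signal = NULL) {
  stopifnot(inherits(series, "ctiq_series"), inherits(ir, "ctiq_ir"))
  if (ir$alpha < 0 || ir$alpha > 1) stopf("alpha must be in [0, 1]")
  meta <- series$meta
  meta$recon_method <- if (ir$level == 0) "FBP" else "IR"
  meta$recon_label <- ir$label
  if (ir$level == 0 || ir$alpha == 0) {
    series$meta <- meta
    return(series)
  }
  d <- dim(series$voxels)
  rho <- radial_freq_grid(d[1], d[2], series$pixel_spacing)
  h <- (1 - ir$alpha) + ir$alpha * exp(-(rho / ir$f_l)^2)
  npx <- d[1] * d[2]
  out <- series$voxels
  for (k in seq_len(d[3])) {
    sl <- out[, , k]
    sig <- if (is.null(signal)) 0
    else if (is.matrix(signal)) signal
    else signal[, , k]
    noise <- sl - sig
    out[, , k] <- sig + Re(fft(fft(noise) * h, inverse = TRUE)) / npx
  }
  series$voxels <- out
  series$meta <- meta
  series
}

#' Simulate one acquisition cell (all four phantom modules)
#'
#' Generates the uniformity, sensitometry, low-contrast and edge-disk series
#' for a given scanner, protocol, dose and reconstruction. Noise is shared
#' per module but re-seeded deterministically per (scanner, dose, recon,
#' module) so cells are independent and reproducible.
#'
#' @param profile A [scanner_profile()].
#' @param protocol_class `"body"` or `"brain"`.
#' @param ctdi CTDI_vol in mGy.
#' @param ctdi_ref Reference CTDI_vol in mGy (for noise normalization).
#' @param recon An [ir_emulation()] (level 0 = FBP).
#' @param seed Master seed; per-module seeds are derived from it.
#' @param shape,spacing,n_slices Image geometry.
#' @param blur_sigma System PSF SD in mm used for insert rendering.
#' @param modules Character vector of modules to simulate.
#' @return Named list of `ctiq_series`, one per module, plus `$key`.
#' @export
synth_cell <- function(profile, protocol_class = "body", ctdi, ctdi_ref,
                       recon = ir_emulation(level = 0), seed,
                       shape = c(256, 256), spacing = 1, n_slices = 16,
                       blur_sigma = 0.6,
                       modules = c("uniformity", "sensitometry",
                                   "low_contrast", "edge_disk")) {
  model <- profile_spectrum(profile, protocol_class)
  fov <- min(shape * rep(spacing, length.out = 2))
  out <- list()
  for (mod in modules) {
    sd_seed <- cell_seed(seed, profile$name, protocol_class, ctdi,
                         recon$label, mod)
    meta <- acquisition_meta(
      scanner_id = profile$name, protocol_class = protocol_class,
      ctdi_vol = ctdi, recon_method = "FBP", recon_label = "FBP")
    s <- synth_noise_series(model, ctdi = ctdi, ctdi_ref = ctdi_ref,
                            efficiency = profile$efficiency, shape = shape,
                            spacing = spacing, n_slices = n_slices,
                            seed = sd_seed, meta = meta)
    layout <- catphan_layout(mod, fov = fov)
    sig <- if (length(layout)) {
      render_inserts(shape, rep(spacing, length.out = 2), layout,
                     blur_sigma = blur_sigma)
    } else NULL
    if (!is.null(sig)) s$voxels <- s$voxels + as.vector(sig)
    s <- emulate_ir(s, recon, signal = sig)
    attr(s, "layout") <- layout
    out[[mod]] <- s
  }
  out$key <- list(scanner = profile$name, protocol_class = protocol_class,
                  ctdi_vol = ctdi, recon_label = recon$label)
  out
}

#' Simulate a full two-scanner study
#'
#' Full factorial (scanner x CTDI_vol x reconstruction) of the four phantom
#' modules, the acquisition design of a protocol-harmonization experiment.
#' Every cell derives its seed deterministically from the master seed and
#' its labels, so the whole collection is reproducible and cells are
#' mutually independent.
#'
#' @param profiles List of [scanner_profile()] objects (typically two).
#' @param protocol_class `"body"` or `"brain"`.
#' @param ctdi_list Numeric vector of CTDI_vol values in mGy (non-empty).
#' @param recons List of [ir_emulation()] objects (include level 0 for FBP).
#' @param seed Master seed.
#' @param ctdi_ref Reference dose for noise normalization; defaults to the
#'   median of `ctdi_list`.
#' @param ... Geometry arguments passed to [synth_cell()].
#' @return List of cells (class `ctiq_study`) with a `manifest` attribute
#'   (data frame of scanner, ctdi, recon, seed per cell).
#' @export
synth_study <- function(profiles, protocol_class = "body",
                        ctdi_list, recons, seed, ctdi_ref = NULL, ...) {
  if (!length(ctdi_list)) stopf("ctdi_list must be non-empty")
  if (!length(recons)) stopf("recons must be non-empty")
  if (inherits(profiles, "ctiq_scanner")) profiles <- list(profiles)
  ctdi_ref <- ctdi_ref %||% stats::median(ctdi_list)
  cells <- list()
  manifest <- NULL
  for (pr in profiles) {
    for (ctdi in ctdi_list) {
      for (rec in recons) {
        cell <- synth_cell(pr, protocol_class = protocol_class, ctdi = ctdi,
                           ctdi_ref = ctdi_ref, recon = rec, seed = seed, ...)
        cells[[length(cells) + 1L]] <- cell
        manifest <- rbind(manifest, data.frame(
          scanner = pr$name, protocol_class = protocol_class,
          ctdi_vol = ctdi, recon_label = rec$label,
          seed = cell_seed(seed, pr$name, protocol_class, ctdi, rec$label,
                           "uniformity"),
          stringsAsFactors = FALSE))
      }
    }
  }
  structure(cells, class = "ctiq_study", manifest = manifest)
}
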