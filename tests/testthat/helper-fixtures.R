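# Shared fixtures: everything is generated in code, seeded, and small.

white_series <- function(n = 128, n_slices = 8, sd = 10, seed = 1,
                         spacing = 1) {
  set.seed(seed)
  image_series(array(stats::rnorm(n * n * n_slices, sd = sd),
                     c(n, n, n_slices)),
               pixel_spacing = c(spacing, spacing))
}

std_model <- function(target_sd = 10) {
  noise_spectrum_model(corner_freq = 0.35, sharpness = 2,
                       target_sd = target_sd)
}

# analytic Gaussian-blurred circular edge rendered point-sampled (no pixel
# aperture), for closed-form TTF work
blurred_edge_image <- function(sigma = 0.8, n = 512, spacing = 0.5,
                               diameter = 30, delta_hu = 25,
                               center = c(0.155, -0.11)) {
  ins <- insert_spec(center, diameter = diameter, delta_hu = delta_hu,
                     label = "edge")
  img <- render_inserts(c(n, n), c(spacing, spacing), list(ins),
                        blur_sigma = sigma, supersample = 1)
  attr(img, "pixel_spacing") <- c(spacing, spacing)
  list(img = img, insert = ins)
}

# synthetic ESF object directly from a functional form
esf_from_fun <- function(f, r = seq(-4, 4, by = 0.05), delta_hu = 25) {
  structure(list(r = r, value = f(r), n_per_bin = rep(10, length(r)),
                 delta_hu = delta_hu, radius = 6, center = c(0, 0),
                 bin_width = r[2] - r[1]),
            class = "ctiq_esf")
}
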