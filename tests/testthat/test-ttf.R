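test_that("the ESF of a blurred circular edge follows the analytic profile", {
  be <- blurred_edge_image(sigma = 0.8)
  esf <- extract_esf(be$img, be$insert, band_mm = 5, bin_width = 0.05)
  # a Gaussian-blurred (large-radius) edge is a scaled normal CDF in the
  # signed distance from the edge
  expected <- 25 * stats::pnorm(-esf$r / 0.8)
  rms <- sqrt(mean((esf$value - expected)^2))
  expect_lt(rms, 0.5)
  expect_gte(min(abs(range(esf$r))), 3)
})

test_that("an unblurred edge transitions within about one pixel", {
  ins <- insert_spec(c(0.31, -0.22), diameter = 16, delta_hu = 50,
                     label = "sharp")
  img <- render_inserts(c(128, 128), c(1, 1), list(ins), blur_sigma = 0)
  attr(img, "pixel_spacing") <- c(1, 1)
  esf <- extract_esf(img, ins)
  expect_true(all(esf$value[esf$r < -1] > 49))
  expect_true(all(esf$value[esf$r > 1] < 1))
})

test_that("pure noise with no disk is rejected, never a silent TTF", {
  set.seed(77)
  img <- matrix(rnorm(64 * 64, sd = 2), 64, 64)
  attr(img, "pixel_spacing") <- c(1, 1)
  ins <- insert_spec(c(0, 0), 12, 25, "missing")
  expect_error(extract_esf(img, ins), "not found")
})

test_that("the edge model subsumes a pure sigmoid", {
  esf <- esf_from_fun(function(r) 25 / (1 + exp(r / 0.4)))
  fit <- fit_esf_ott(esf)
  expect_lt(abs(fit$par[["a1"]]), 0.01 * 25)
  expect_lt(abs(fit$par[["a2"]]), 0.01 * 25)
  expect_equal(fit$par[["amp"]], 25, tolerance = 1e-3)
  expect_lt(fit$rms_residual, 1e-6)
})

test_that("planted overshoot parameters are recovered within 5%", {
  esf <- esf_from_fun(function(r) {
    25 / (1 + exp(r / 0.4)) + 2 * exp(-(r - 0.8)^2 / (2 * 0.5^2))
  })
  fit <- fit_esf_ott(esf)
  p <- fit$par
  expect_equal(p[["amp"]], 25, tolerance = 0.05)
  expect_equal(p[["width"]], 0.4, tolerance = 0.05)
  # the overshoot lobe lands in one of the two Gaussian slots
  g <- if (abs(p[["a1"]]) > abs(p[["a2"]])) c("a1", "c1", "w1")
  else c("a2", "c2", "w2")
  expect_equal(p[[g[1]]], 2, tolerance = 0.05)
  expect_equal(p[[g[2]]], 0.8, tolerance = 0.05)
  expect_equal(p[[g[3]]], 0.5, tolerance = 0.05)
})

test_that("a Gaussian-blurred edge recovers the closed-form TTF and f50", {
  sigma <- 0.8
  be <- blurred_edge_image(sigma = sigma)
  esf <- extract_esf(be$img, be$insert, band_mm = 5, bin_width = 0.05)
  tt <- compute_ttf(esf, mode = "direct")
  truth <- exp(-2 * pi^2 * sigma^2 * tt$rho^2)
  keep <- truth >= 0.1
  expect_lt(max(abs(tt$value - truth)[keep] / truth[keep]), 0.02)
  expect_equal(tt$f50, sqrt(log(2) / (2 * pi^2 * sigma^2)),
               tolerance = 0.03)

  # parametric and direct routes agree at low frequency on noiseless edges
  tto <- compute_ttf(esf, mode = "ott")
  k <- tt$rho <= tt$f50
  l2 <- sqrt(sum((tt$value[k] - tto$value[k])^2) / sum(tt$value[k]^2))
  expect_lt(l2, 0.03)
})

test_that("TTF is invariant to contrast sign and global HU offset", {
  be_pos <- blurred_edge_image(sigma = 0.6, delta_hu = 25)
  be_neg <- blurred_edge_image(sigma = 0.6, delta_hu = -25)
  esf_p <- extract_esf(be_pos$img, be_pos$insert, band_mm = 4)
  esf_n <- extract_esf(be_neg$img, be_neg$insert, band_mm = 4)
  tp <- compute_ttf(esf_p, mode = "direct")
  tn <- compute_ttf(esf_n, mode = "direct")
  expect_equal(tp$value, tn$value, tolerance = 1e-8)

  img_off <- be_pos$img + 500
  attr(img_off, "pixel_spacing") <- attr(be_pos$img, "pixel_spacing")
  esf_o <- extract_esf(img_off, be_pos$insert, band_mm = 4)
  to <- compute_ttf(esf_o, mode = "direct")
  expect_equal(to$value, tp$value, tolerance = 1e-8)
})

test_that("more blur means strictly lower f50", {
  f50s <- vapply(c(0.4, 0.6, 0.9, 1.2), function(sig) {
    be <- blurred_edge_image(sigma = sig)
    compute_ttf(extract_esf(be$img, be$insert, band_mm = 5,
                            bin_width = 0.05),
                mode = "direct")$f50
  }, numeric(1))
  expect_true(all(diff(f50s) < 0))
})

test_that("on noisy low-CNR edges the fitted TTF beats differentiation", {
  sigma <- 0.8
  ins <- insert_spec(c(0.155, -0.11), diameter = 30, delta_hu = 10,
                     label = "edge")
  sig <- render_inserts(c(256, 256), c(0.5, 0.5), list(ins),
                        blur_sigma = sigma, supersample = 1)
  errs <- vapply(1:5, function(seed) {
    set.seed(seed)
    img <- sig + matrix(rnorm(256^2, sd = 2), 256, 256)  # CNR ~ 5
    attr(img, "pixel_spacing") <- c(0.5, 0.5)
    esf <- extract_esf(img, ins, band_mm = 5, bin_width = 0.1)
    t_dir <- compute_ttf(esf, mode = "direct")
    t_ott <- compute_ttf(esf, mode = "ott")
    truth <- exp(-2 * pi^2 * sigma^2 * t_dir$rho^2)
    keep <- t_dir$rho <= 0.6
    err <- function(tt) sqrt(sum((tt$value[keep] - truth[keep])^2))
    c(dir = err(t_dir), ott = err(t_ott))
  }, numeric(2))
  expect_lt(mean(errs["ott", ]), mean(errs["dir", ]))
})

test_that("the automatic mode gate follows the measured CNR", {
  be <- blurred_edge_image(sigma = 0.8)
  esf <- extract_esf(be$img, be$insert, band_mm = 4)
  expect_equal(compute_ttf(esf, mode = "auto", cnr = 5)$mode, "ott")
  expect_equal(compute_ttf(esf, mode = "auto", cnr = 40)$mode, "direct")
})
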