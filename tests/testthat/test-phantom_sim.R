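test_that("synthetic noise hits its target SD and the dose law", {
  m <- std_model(target_sd = 10)
  s1 <- synth_noise_series(m, ctdi = 15, ctdi_ref = 15, shape = c(256, 256),
                           n_slices = 64, seed = 42)
  expect_equal(sd(s1$voxels), 10, tolerance = 0.03)
  expect_lt(abs(mean(s1$voxels)), 0.2)

  s2 <- synth_noise_series(m, ctdi = 30, ctdi_ref = 15, shape = c(256, 256),
                           n_slices = 64, seed = 43)
  expect_equal(sd(s2$voxels) / sd(s1$voxels), 1 / sqrt(2), tolerance = 0.03)

  s3 <- synth_noise_series(m, ctdi = 15, ctdi_ref = 15, efficiency = 0.5,
                           shape = c(128, 128), n_slices = 16, seed = 44)
  expect_equal(sd(s3$voxels) / 10, sqrt(2), tolerance = 0.05)

  expect_error(synth_noise_series(m, ctdi = -1, seed = 1), "positive")
})

test_that("noise synthesis is reproducible for a fixed seed", {
  m <- std_model()
  a <- synth_noise_series(m, ctdi = 10, shape = c(64, 64), n_slices = 2,
                          seed = 9)
  b <- synth_noise_series(m, ctdi = 10, shape = c(64, 64), n_slices = 2,
                          seed = 9)
  expect_identical(a$voxels, b$voxels)
})

test_that("IR emulation is the identity at level 0 and never adds noise", {
  m <- std_model()
  s <- synth_noise_series(m, ctdi = 10, shape = c(128, 128), n_slices = 4,
                          seed = 3)
  s0 <- emulate_ir(s, ir_emulation(level = 0))
  expect_identical(s0$voxels, s$voxels)
  expect_equal(s0$meta$recon_label, "FBP")

  for (lev in 1:4) {
    si <- emulate_ir(s, ir_emulation("hybrid", lev))
    expect_lte(sd(si$voxels), sd(s$voxels))
  }
})

test_that("strong low-pass IR shifts the mean NPS frequency down", {
  s <- white_series(n = 256, n_slices = 8, sd = 10, seed = 21)
  before <- noise_metrics(s)$freq_m
  si <- emulate_ir(s, ir_emulation("custom", 1, alpha = 1, f_l = 0.12))
  after <- noise_metrics(si)$freq_m
  expect_lt(after, before)
})

test_that("IR leaves the deterministic signal untouched", {
  layout <- catphan_layout("edge_disk", fov = 128)
  sig <- render_inserts(c(128, 128), c(1, 1), layout)
  s <- synth_noise_series(std_model(), ctdi = 10, shape = c(128, 128),
                          n_slices = 2, seed = 8)
  s$voxels <- s$voxels + as.vector(sig)
  si <- emulate_ir(s, ir_emulation("model-based", 2), signal = sig)
  comp <- composite_image(si)
  cc <- contrast_cnr(comp, layout)
  expect_equal(cc$contrast[1], 25, tolerance = 1)
})

test_that("phantom layouts carry the reference insert specifications", {
  sens <- catphan_layout("sensitometry", fov = 256)
  expect_length(sens, 7)
  expect_equal(sens$Acrylic$delta_hu, 25)
  expect_equal(sens$Teflon$delta_hu, 814)
  expect_equal(sens$Air$delta_hu, -1055)

  edge <- catphan_layout("edge_disk", fov = 256)
  expect_length(edge, 1)
  expect_equal(edge[[1]]$diameter, 12)
  expect_equal(edge[[1]]$delta_hu, 25)

  lc <- catphan_layout("low_contrast", fov = 256)
  expect_equal(lc[[1]]$diameter, 7)
  expect_equal(lc[[1]]$delta_hu, 10)

  expect_length(catphan_layout("uniformity", fov = 256), 0)
  expect_error(catphan_layout("bars", fov = 256))
})

test_that("rendered insert coverage integrates to the disk area", {
  ins <- insert_spec(c(3.3, -2.1), diameter = 12, delta_hu = 100,
                     label = "disk")
  img <- render_inserts(c(128, 128), c(1, 1), list(ins), blur_sigma = 0)
  expect_equal(sum(img) / 100, pi * 36, tolerance = 0.005)
  expect_error(render_inserts(c(32, 32), c(1, 1),
                              list(insert_spec(c(14, 0), 10, 50))),
               "field of view")
})

test_that("a study is a reproducible factorial with ordered noise levels", {
  prA <- scanner_profile("A", efficiency = 1)
  prB <- scanner_profile("B", efficiency = 0.6)
  recons <- list(ir_emulation(level = 0), ir_emulation("hybrid", 2))
  st <- synth_study(list(prA, prB), ctdi_list = c(10, 20), recons = recons,
                    seed = 5, shape = c(64, 64), n_slices = 2,
                    modules = c("uniformity", "edge_disk"))
  expect_length(st, 2 * 2 * 2)
  expect_equal(nrow(attr(st, "manifest")), 8)

  st2 <- synth_study(list(prA, prB), ctdi_list = c(10, 20), recons = recons,
                     seed = 5, shape = c(64, 64), n_slices = 2,
                     modules = c("uniformity", "edge_disk"))
  expect_identical(st[[1]]$uniformity$voxels, st2[[1]]$uniformity$voxels)

  # lower efficiency => more noise in every matched cell
  for (i in 1:4) {
    a <- st[[i]]
    b <- st[[i + 4]]
    expect_equal(a$key$ctdi_vol, b$key$ctdi_vol)
    expect_gt(sd(b$uniformity$voxels), sd(a$uniformity$voxels))
  }
})

test_that("the empirical NPS of synthetic noise matches the planted shape", {
  m <- std_model(target_sd = 10)
  s <- synth_noise_series(m, ctdi = 15, shape = c(256, 256), n_slices = 32,
                          seed = 42)
  nm <- noise_metrics(s)
  g_full <- m$eval(ctiq:::radial_freq_grid(256, 256, c(1, 1)))
  expected <- 100 * m$eval(nm$nps1d$rho) / mean(g_full)
  l2 <- sqrt(sum((nm$nps1d$values - expected)^2) / sum(expected^2))
  expect_lt(l2, 0.05)
})
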