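test_that("image_series validates geometry and metadata", {
  expect_error(image_series(array(NA_real_, c(4, 4, 1))), "finite")
  expect_error(image_series(array(0, c(4, 4, 2)), pixel_spacing = c(0, 1)),
               "positive")
  expect_error(image_series(array(0, c(4, 4, 3)),
                            slice_positions = c(0, 2, 1)),
               "monotone")
  expect_error(acquisition_meta(ctdi_vol = -5), "ctdi_vol")
  s <- image_series(matrix(0, 8, 8))
  expect_equal(dim(s$voxels), c(8, 8, 1))
})

test_that("fixture round trip is bit-exact and deterministic", {
  s <- white_series(n = 24, n_slices = 3, seed = 7)
  s$voxels <- round(s$voxels)
  b1 <- write_fixture(s, tempfile())
  s2 <- read_fixture(b1)
  expect_identical(s2$voxels, s$voxels)
  expect_equal(s2$pixel_spacing, s$pixel_spacing)
  expect_equal(s2$slice_positions, s$slice_positions)
  expect_equal(s2$meta$ctdi_vol, s$meta$ctdi_vol)

  b2 <- write_fixture(s, tempfile())
  expect_identical(readBin(paste0(b1, ".raw"), "raw", n = 1e6),
                   readBin(paste0(b2, ".raw"), "raw", n = 1e6))
  expect_identical(readLines(paste0(b1, ".json")),
                   readLines(paste0(b2, ".json")))
})

test_that("fixture rejects out-of-range HU and incomplete sidecars", {
  s <- image_series(array(40000, c(8, 8, 1)))
  expect_error(write_fixture(s, tempfile()), "int16")

  s2 <- white_series(n = 16, n_slices = 1)
  s2$voxels <- round(s2$voxels)
  base <- write_fixture(s2, tempfile())
  sidecar <- jsonlite::fromJSON(paste0(base, ".json"))
  sidecar$pixel_spacing <- NULL
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE),
             paste0(base, ".json"))
  expect_error(read_fixture(base), "pixel_spacing")
})

test_that("DICOM round trip preserves voxels, spacing and metadata", {
  s <- synth_noise_series(std_model(), ctdi = 10, shape = c(32, 32),
                          n_slices = 4, seed = 5,
                          meta = acquisition_meta("scanX", "brain",
                                                  ctdi_vol = 70,
                                                  recon_method = "IR",
                                                  recon_label = "hybrid-2"))
  s$voxels <- round(s$voxels)
  d <- tempfile()
  write_dicom_series(s, d)
  s2 <- read_dicom_series(d)
  expect_identical(s2$voxels, s$voxels)
  expect_equal(s2$pixel_spacing, s$pixel_spacing, tolerance = 1e-6)
  expect_equal(s2$meta$scanner_id, "scanX")
  expect_equal(s2$meta$protocol_class, "brain")
  expect_equal(s2$meta$ctdi_vol, 70)
  expect_equal(s2$meta$recon_label, "hybrid-2")
})

test_that("DICOM HU conversion applies rescale slope and intercept", {
  s <- image_series(array(-1024, c(16, 16, 3)))
  d <- tempfile()
  write_dicom_series(s, d, slope = 1, intercept = -1024)
  got <- read_dicom_series(d)
  expect_true(all(got$voxels == -1024))
})

test_that("DICOM slices are ordered by position, not by file name", {
  s <- image_series(array(rep(c(10, 20, 30), each = 64), c(8, 8, 3)),
                    slice_positions = c(0, 2, 4))
  d <- tempfile()
  write_dicom_series(s, d)
  # rename so lexicographic file order is the reverse of spatial order
  files <- list.files(d, full.names = TRUE)
  tmp <- file.path(d, c("c.dcm", "b.dcm", "a.dcm"))
  file.rename(files, tmp)
  got <- read_dicom_series(d)
  expect_equal(got$voxels[1, 1, ], c(10, 20, 30))
  expect_equal(got$slice_positions, c(0, 2, 4))
})

test_that("DICOM reader rejects mixed series and missing rescale tags", {
  s1 <- image_series(array(0, c(8, 8, 1)))
  s2 <- image_series(array(0, c(8, 8, 2)))
  d <- tempfile()
  write_dicom_series(s1, d)
  d2 <- tempfile()
  write_dicom_series(s2, d2)
  file.copy(file.path(d2, "slice_0002.dcm"),
            file.path(d, "extra.dcm"))
  expect_error(read_dicom_series(d), "mixed")

  # strip the rescale tags by truncating at the (0028,1052) element
  d3 <- tempfile()
  write_dicom_series(s1, d3)
  f <- list.files(d3, full.names = TRUE)[1]
  bytes <- readBin(f, "raw", file.info(f)$size)
  pat <- as.raw(c(0x28, 0x00, 0x52, 0x10))
  hit <- which(bytes == pat[1])
  hit <- hit[bytes[hit + 1] == pat[2] & bytes[hit + 2] == pat[3] &
               bytes[hit + 3] == pat[4]][1]
  # overwrite the tag with an unknown private tag so it is ignored
  bytes[hit:(hit + 3)] <- as.raw(c(0x29, 0x00, 0x52, 0x10))
  writeBin(bytes, f)
  expect_error(read_dicom_series(d3), "rescale")
})

test_that("NPS metrics are preserved through a DICOM round trip", {
  s <- synth_noise_series(std_model(), ctdi = 10, shape = c(128, 128),
                          n_slices = 4, seed = 11)
  s$voxels <- round(s$voxels)  # integral HU so DICOM storage is lossless
  direct <- noise_metrics(s, roi_grid(32, 16))
  d <- tempfile()
  write_dicom_series(s, d)
  rt <- noise_metrics(read_dicom_series(d), roi_grid(32, 16))
  for (f in c("noise_sd", "nps_p", "freq_p", "freq_m", "auc_nps")) {
    expect_equal(rt[[f]], direct[[f]], tolerance = 1e-6)
  }
})
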