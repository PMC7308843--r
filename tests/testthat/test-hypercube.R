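# Calibration, band cropping, segmentation, spectra and on-disk formats.

make_cube <- function(vals, wl) {
  hypercube(array(vals, c(4, 4, length(wl))), wl, "raw")
}

test_that("reference calibration handles the canonical fixed points", {
  wl <- c(500, 600, 700)
  white <- array(4000, c(4, 4, 3)); dark <- array(100, c(4, 4, 3))
  refs <- reference_frames(white, dark)
  expect_equal(calibrate(make_cube(100, wl), refs)$data,
               array(0, c(4, 4, 3)))
  expect_equal(calibrate(make_cube(4000, wl), refs)$data,
               array(1, c(4, 4, 3)))
  expect_equal(calibrate(make_cube(2050, wl), refs)$data,
               array(0.5, c(4, 4, 3)))
})

test_that("calibration is invariant to a shared affine counts distortion", {
  wl <- c(500, 600)
  set.seed(4)
  raw <- array(runif(32, 500, 3000), c(4, 4, 2))
  white <- array(4000, c(4, 4, 2)); dark <- array(100, c(4, 4, 2))
  r1 <- calibrate(hypercube(raw, wl, "raw"), reference_frames(white, dark))
  r2 <- calibrate(hypercube(3 * raw + 7, wl, "raw"),
                  reference_frames(3 * white + 7, 3 * dark + 7))
  expect_equal(r1$data, r2$data, tolerance = 1e-12)
})

test_that("equal white and dark elements raise a guard error", {
  wl <- c(500, 600)
  white <- array(4000, c(4, 4, 2)); white[2, 2, 1] <- 100
  expect_error(calibrate(make_cube(200, wl),
                         reference_frames(white, array(100, c(4, 4, 2)))),
               "white == dark")
})

test_that("band cropping keeps a closed interval and composes", {
  wl <- c(395, 400, 500, 1000, 1005)
  cube <- make_cube(seq_len(4 * 4 * 5), wl)
  full <- crop_bands(cube, 390, 1010)
  expect_identical(full$wavelengths, wl)
  inner <- crop_bands(cube, 400, 1000)
  expect_identical(inner$wavelengths, c(400, 500, 1000))
  # nested crops collapse to the inner window
  expect_identical(crop_bands(crop_bands(cube, 398, 1002), 400, 1000),
                   inner)
  expect_error(crop_bands(cube, 600, 650), "no bands")
  expect_error(crop_bands(cube, 700, 600), "lo")
})

test_that("the native grid yields a stable 400-1000 nm band count", {
  wl <- default_wavelengths()
  n <- sum(wl >= 400 & wl <= 1000)
  expect_identical(n, 259L)
  sc <- small_scene(seed = 2L)
  cube <- crop_bands(calibrate(as_hypercube(sc), reference_frames(sc)))
  expect_identical(length(cube$wavelengths), n)
})

test_that("nearest-band resolution breaks ties toward the lower band", {
  wl <- c(400, 410, 420)
  expect_identical(resolve_bands(wl, c(403, 405, 409, 416)),
                   c(1L, 1L, 2L, 3L))
})

test_that("super-red segmentation finds the fruit and rejects gray scenes", {
  wl <- c(457, 531, 691)
  arr <- array(0.1, c(5, 5, 3))
  arr[2:3, 2:3, 3] <- 0.8   # red-bright block
  cube <- hypercube(arr, wl, "reflectance")
  m <- segment_superred(cube, c(691, 531, 457), threshold = 0.5)
  expect_true(all(m$mask[2:3, 2:3]))
  expect_identical(m$pixel_count, 4L)
  gray <- hypercube(array(0.4, c(5, 5, 3)), wl, "reflectance")
  expect_error(segment_superred(gray, c(691, 531, 457), threshold = 0.1),
               "empty mask")
})

test_that("segmentation keeps only the largest connected component", {
  wl <- c(457, 531, 691)
  arr <- array(0.1, c(7, 7, 3))
  arr[2:5, 2:5, 3] <- 0.8
  arr[7, 7, 3] <- 0.9       # speck, 4-disconnected from the block
  cube <- hypercube(arr, wl, "reflectance")
  m <- segment_superred(cube, c(691, 531, 457), threshold = 0.5)
  expect_false(m$mask[7, 7])
  expect_identical(m$pixel_count, 16L)
})

test_that("segmentation of a default synthetic scene overlaps the truth mask", {
  sc <- small_scene(seed = 12L)
  cube <- calibrate(as_hypercube(sc), reference_frames(sc))
  m <- segment_superred(cube)
  iou <- sum(m$mask & sc$truth_mask) / sum(m$mask | sc$truth_mask)
  expect_gte(iou, 0.95)
})

test_that("mean spectrum averages masked pixels and is linear", {
  wl <- c(500, 600)
  arr <- array(0.2, c(2, 2, 2)); arr[2, 1, ] <- 0.4
  cube <- hypercube(arr, wl, "reflectance")
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(mean_spectrum(cube, mask), c(0.3, 0.3))
  one <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(mean_spectrum(cube, one), c(0.4, 0.4))
  # linearity in the cube argument
  c2 <- hypercube(arr * 2, wl, "reflectance")
  sum_cube <- hypercube(arr + arr * 2, wl, "reflectance")
  expect_equal(mean_spectrum(sum_cube, mask),
               mean_spectrum(cube, mask) + mean_spectrum(c2, mask))
  expect_error(mean_spectrum(cube, mask & FALSE), "empty")
})

test_that("ENVI header + BSQ round-trip preserves data and wavelengths", {
  set.seed(8)
  cube <- hypercube(array(runif(4 * 5 * 6), c(4, 5, 6)),
                    seq(400, 900, 100), "reflectance")
  path <- file.path(tempdir(), "cube_rt")
  write_envi(cube, path)
  back <- read_envi(path)
  expect_equal(back$data, cube$data, tolerance = 0)
  expect_identical(back$wavelengths, cube$wavelengths)
  expect_identical(back$kind, "reflectance")
  # header without a wavelength list is a format error
  hdr <- readLines(paste0(path, ".hdr"))
  writeLines(hdr[!grepl("wavelength", hdr)], paste0(path, ".hdr"))
  expect_error(read_envi(path), "wavelength")
})

test_that("scene container and mask PNG round-trip", {
  sc <- small_scene(seed = 4L)
  p <- file.path(tempdir(), "scene.rds")
  write_scene(sc, p)
  expect_identical(read_scene(p), sc)
  mp <- file.path(tempdir(), "mask.png")
  write_mask_png(sc$truth_mask, mp)
  expect_equal(png::readPNG(mp) > 0.5, unname(sc$truth_mask))
})
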