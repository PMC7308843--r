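# Color moments, GLGCM, Gabor and feature assembly.

rgb_cube <- function(r, g, b, n = 4) {
  arr <- array(0, c(n, n, 3))
  arr[, , 1] <- b; arr[, , 2] <- g; arr[, , 3] <- r
  hypercube(arr, c(457, 531, 691), "reflectance")
}

test_that("color moments capture mean, spread and symmetry per channel", {
  cube <- rgb_cube(0.8, 0.5, 0.2)
  mask <- matrix(TRUE, 4, 4)
  cm <- color_moments(cube, mask)
  expect_length(cm, 9)
  expect_equal(unname(cm), c(0.8, 0, 0, 0.5, 0, 0, 0.2, 0, 0))
  # two-pixel channel {0, 2}: mean 1, sd 1, zero skew
  arr <- array(0.1, c(2, 1, 3))
  arr[, 1, 3] <- c(0, 2)
  cube2 <- hypercube(arr, c(457, 531, 691), "reflectance")
  cm2 <- color_moments(cube2, matrix(TRUE, 2, 1))
  expect_equal(unname(cm2[1:3]), c(1, 1, 0))
  expect_error(color_moments(cube, mask & FALSE), "empty")
})

test_that("GLGCM of a constant image is a single occupied cell", {
  f <- glgcm_features(matrix(0.7, 8, 8))
  expect_length(f, 15)
  expect_identical(names(f), glgcm_feature_names())
  expect_equal(unname(f["energy"]), 1)
  expect_equal(unname(f[c("gray_entropy", "grads_entropy", "entropy")]),
               c(0, 0, 0))
  expect_equal(unname(f["small_grads_dominance"]), 1)   # grad level 1
  # single cell at (gray 16, grad 1): homogeneity = 1 / (1 + 15^2)
  expect_equal(unname(f["homogeneity"]), 1 / 226)
})

test_that("GLGCM matches the brute-force joint-table oracle", {
  # checkerboard of two gray values
  cb <- matrix(rep(c(0.2, 0.9), 8), 4, 4)
  expect_equal(unname(glgcm_features(cb)), glgcm_oracle(cb),
               tolerance = 1e-12)
  # 200 seeded random 8x8 images
  for (s in 1:200) {
    set.seed(s)
    img <- matrix(runif(64), 8, 8)
    expect_equal(unname(glgcm_features(img)), glgcm_oracle(img),
                 tolerance = 1e-10)
  }
})

test_that("GLGCM statistics respect their analytic ranges", {
  set.seed(42)
  for (i in 1:25) {
    img <- matrix(runif(144), 12, 12)
    f <- glgcm_features(img)
    expect_gt(f[["energy"]], 0); expect_lte(f[["energy"]], 1)
    expect_gte(f[["gray_entropy"]], 0)
    expect_gte(f[["grads_entropy"]], 0)
    expect_gte(f[["entropy"]], 0)
    expect_gt(f[["homogeneity"]], 0); expect_lte(f[["homogeneity"]], 1)
  }
})

test_that("texture features ignore everything outside the mask", {
  set.seed(13)
  img <- matrix(runif(400), 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[3:17, 3:17] <- TRUE
  f1 <- glgcm_features(img, mask)
  g1 <- gabor_features(img, mask, sigma = c(1, 2))
  img2 <- img
  img2[!mask] <- runif(sum(!mask))   # scramble the background
  expect_equal(glgcm_features(img2, mask), f1, tolerance = 1e-12)
  expect_equal(gabor_features(img2, mask, sigma = c(1, 2)), g1,
               tolerance = 1e-12)
})

test_that("the Gabor kernel has zero DC gain and orientation selectivity", {
  g3 <- gabor_features(matrix(0.3, 40, 40))
  expect_length(g3, 3)
  expect_lt(abs(g3[["gabor_mean"]]), 1e-8)
  expect_lt(abs(g3[["gabor_contrast"]]), 1e-8)
  xs <- 1:60
  grat <- function(th) outer(xs, xs, function(r, c)
    sin(2 * pi * 0.25 * (c * cos(th) + r * sin(th))))
  r60 <- gabor_features(grat(pi / 3))[["gabor_mean"]]
  r150 <- gabor_features(grat(5 * pi / 6))[["gabor_mean"]]
  expect_gt(r60, r150 * 10)
})

test_that("gabor rejects masks smaller than the kernel support", {
  expect_error(gabor_features(matrix(runif(64), 8, 8)), "kernel")
})

test_that("texture block concatenates two bands of GLGCM + Gabor", {
  sc <- small_scene(seed = 6L)
  cube <- calibrate(as_hypercube(sc), reference_frames(sc))
  mask <- segment_superred(cube)
  tb <- texture_block(cube, mask, c(676, 910))
  expect_length(tb, 36)
  # identical images at both requested bands: duplicate a wavelength
  tb2 <- texture_block(cube, mask, c(910, 910))
  expect_equal(unname(tb2[1:18]), unname(tb2[19:36]), tolerance = 1e-12)
  # the configured pairs resolve to the nearest grid bands
  b <- resolve_bands(cube$wavelengths, texture_band_pairs()$ssc)
  expect_equal(cube$wavelengths[b], c(676, 910), tolerance = 1.2)
})

test_that("feature assembly concatenates aligned blocks in order", {
  wl <- default_wavelengths()[1:20]
  sp <- spectra_table(matrix(runif(60), 3), wl,
                      ids = c("A", "B", "C"))
  only <- assemble_features(sp, include = "spectral")
  expect_equal(unname(only$F), unname(sp$X))
  color <- matrix(runif(27), 3, dimnames = list(c("A", "B", "C"), NULL))
  texture <- matrix(runif(108), 3, dimnames = list(c("A", "B", "C"), NULL))
  fused <- assemble_features(sp, color = color, texture = texture)
  expect_identical(ncol(fused$F), 20L + 9L + 36L)
  expect_identical(fused$blocks,
                   c(rep("spectral", 20), rep("color", 9),
                     rep("texture", 36)))
  two <- assemble_features(sp, color = color,
                           include = c("spectral", "color"))
  expect_identical(ncol(two$F), 29L)
  bad <- color; rownames(bad) <- c("A", "B", "X")
  expect_error(assemble_features(sp, color = bad,
                                 include = c("spectral", "color")), "align")
})

test_that("feature tables round-trip through the two-header CSV", {
  wl <- default_wavelengths()[1:5]
  sp <- spectra_table(matrix(runif(10), 2), wl, ids = c("A", "B"))
  color <- matrix(runif(18), 2, dimnames = list(c("A", "B"), NULL))
  ft <- assemble_features(sp, color = color,
                          include = c("spectral", "color"))
  p <- file.path(tempdir(), "features.csv")
  write_features_csv(ft, p)
  back <- read_features_csv(p)
  expect_equal(unname(back$F), unname(ft$F), tolerance = 1e-12)
  expect_identical(back$blocks, ft$blocks)
  expect_identical(back$ids, ft$ids)
  expect_equal(back$wavelengths, ft$wavelengths)
})
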