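# Forward model, assay arithmetic and scene/dataset generation.

test_that("forward model reduces to the fixed baseline at zero effect", {
  wl <- default_wavelengths()
  cfg <- forward_model_config()
  # midpoint latents: every effect term is multiplied by z = 0
  r_mid <- spectral_forward_model(latent_midpoint(), wl, cfg)
  zero <- cfg
  for (nm in names(zero$effects))
    for (k in seq_along(zero$effects[[nm]])) zero$effects[[nm]][[k]]$amp <- 0
  r_zero <- spectral_forward_model(latent_quality(8, 2.7, 0.5), wl, zero)
  expect_identical(r_mid, berryhsi:::.baseline_spectrum(wl, cfg))
  expect_identical(r_zero, berryhsi:::.baseline_spectrum(wl, zero))
})

test_that("latents act only through their own spectral windows", {
  wl <- default_wavelengths()
  cfg <- forward_model_config()
  q1 <- latent_quality(4.0, 3.0, 0.65)
  q2 <- latent_quality(8.0, 3.0, 0.65)
  d <- abs(spectral_forward_model(q2, wl, cfg) -
           spectral_forward_model(q1, wl, cfg))
  # Gaussian components fall below 1e-10 only past ~6.5 sigma
  inside <- rep(FALSE, length(wl))
  for (cp in cfg$effects$ssc)
    inside <- inside | abs(wl - cp$center) <= 7 * cp$width
  expect_gt(max(d[inside]), 0.01)
  expect_lt(max(d[!inside]), 1e-10)
})

test_that("reflectance stays in (0,1) over the latent space", {
  wl <- default_wavelengths()
  set.seed(31)
  for (i in 1:1000) {
    q <- latent_quality(runif(1, 3.4, 8.4), runif(1, 2.68, 3.33),
                        runif(1, 0.4745, 0.8421))
    r <- spectral_forward_model(q, wl)
    expect_true(all(r > 0 & r < 1))
  }
})

test_that("chlorophyll dip depth is monotone in soluble solids", {
  wl <- default_wavelengths()
  b680 <- resolve_bands(wl, 680)
  depth <- vapply(seq(3.5, 8.3, length.out = 9), function(s) {
    r <- spectral_forward_model(latent_quality(s, 3.0, 0.65), wl)
    # dip depth relative to a linear interpolation across the 680 window
    shoulder <- mean(r[resolve_bands(wl, c(600, 760))])
    shoulder - r[b680]
  }, numeric(1))
  expect_true(all(diff(depth) > 0))
})

test_that("wavelengths outside the supported range are rejected", {
  expect_error(spectral_forward_model(latent_midpoint(), c(300, 500)),
               "range")
  expect_error(latent_quality(9.5, 3.0, 0.65), "ssc")
})

test_that("vitamin C content follows the assay formula", {
  expect_identical(vc_content(0, 10, 20), 0)
  for (x in c(0, 0.3, 1.7)) expect_equal(vc_content(x, 5, 5), 1000 * x)
  expect_equal(vc_content(1.28e-3, 10, 20), 0.64)
  expect_error(vc_content(1e-3, 0, 20), "V")
  expect_error(vc_content(1e-3, 10, 0), "M")
  expect_error(vc_content(-1, 10, 20), "C")
})

test_that("calibration inverts noiseless scene generation exactly", {
  clean <- scene_config(noise_sd = 0, scatter_offset_sd = 0,
                        scatter_slope_sd = 0)
  sc <- small_scene(seed = 3L, noise = clean)
  cube <- calibrate(as_hypercube(sc), reference_frames(sc))
  wl <- sc$wavelengths
  idx <- which(sc$truth_mask)
  d <- dim(cube$data)
  px <- matrix(cube$data, d[1] * d[2], d[3])[idx, ]
  # per-pixel expectation includes the planted within-fruit SSC gradient
  err <- vapply(seq_along(idx), function(k) {
    qpx <- latent_quality(sc$truth_maps$ssc[idx[k]], sc$truth$ph, sc$truth$vc)
    max(abs(px[k, ] - spectral_forward_model(qpx, wl)))
  }, numeric(1))
  expect_lt(max(err), 1e-10)
})

test_that("scene generation is reproducible per seed", {
  a <- small_scene(seed = 17L)
  b <- small_scene(seed = 17L)
  expect_identical(a, b)
  expect_false(identical(a$raw_cube, small_scene(seed = 18L)$raw_cube))
})

test_that("ROI-mean calibrated spectrum tracks the forward model at default noise", {
  sc <- small_scene(seed = 23L)
  cube <- calibrate(as_hypercube(sc), reference_frames(sc))
  m <- mean_spectrum(cube, sc$truth_mask)
  expected <- spectral_forward_model(sc$truth, sc$wavelengths)
  npx <- sum(sc$truth_mask)
  cfg <- sc$config
  band_sd <- sqrt(cfg$scatter_offset_sd^2 + cfg$scatter_slope_sd^2 * expected^2 +
                  cfg$noise_sd^2) / sqrt(npx)
  z <- abs(m - expected) / band_sd
  expect_lt(mean(z), 3)    # aggregate CLT bound
  expect_lt(max(z), 6)     # no band wildly off
})

test_that("dataset generation honours groups, ranges and storage drift", {
  truth <- generate_truth(120L, 5L, seed = 7L)
  expect_identical(as.vector(table(truth$group)), rep(24L, 5))
  expect_true(all(truth$ssc >= 3.4 & truth$ssc <= 8.4))
  expect_true(all(truth$ph >= 2.68 & truth$ph <= 3.33))
  expect_true(all(truth$vc >= 0.4745 & truth$vc <= 0.8421))
  mph <- tapply(truth$ph, truth$group, mean)
  mvc <- tapply(truth$vc, truth$group, mean)
  mssc <- tapply(truth$ssc, truth$group, mean)
  expect_true(all(diff(mph) < 0))            # pH declines through storage
  expect_true(all(diff(mvc) < 0))            # VC declines
  expect_true(which.max(mssc) %in% 2:4)      # SSC rises then falls
  expect_error(generate_truth(121L, 5L), "divisible")
  expect_identical(generate_truth(40L, 5L, seed = 3L),
                   generate_truth(40L, 5L, seed = 3L))
})
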