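# Synthetic storage-experiment generator: latent fruit quality -> reflectance
# spectra -> raw hypercubes with reference frames, scatter and noise.

# Observed ranges of the three quality parameters across a 120-fruit storage
# experiment (soluble solids %, pH, vitamin C g/kg).
.quality_ranges <- list(
  ssc = c(3.4, 8.4),
  ph  = c(2.68, 3.33),
  vc  = c(0.4745, 0.8421)
)

#' Latent fruit quality
#'
#' Bundle of the three quality parameters driving the synthetic reflectance
#' model: soluble solid content (SSC, percent), pH (unitless) and vitamin C
#' (VC, g per kg fruit), plus the storage-time group the fruit belongs to.
#'
#' @param ssc soluble solid content in percent, within [3.4, 8.4].
#' @param ph pH, within [2.68, 3.33].
#' @param vc vitamin C in g/kg, within [0.4745, 0.8421].
#' @param storage_group integer storage-time group in 0..4.
#' @return object of class `latent_quality`.
#' @export
latent_quality <- function(ssc, ph, vc, storage_group = 0L) {
  r <- .quality_ranges
  if (ssc < r$ssc[1] || ssc > r$ssc[2]) stop("ssc outside observed range [3.4, 8.4]")
  if (ph  < r$ph[1]  || ph  > r$ph[2])  stop("ph outside observed range [2.68, 3.33]")
  if (vc  < r$vc[1]  || vc  > r$vc[2])  stop("vc outside observed range [0.4745, 0.8421]")
  if (!storage_group %in% 0:4) stop("storage_group must be in 0..4")
  structure(list(ssc = ssc, ph = ph, vc = vc,
                 storage_group = as.integer(storage_group)),
            class = "latent_quality")
}

#' Midpoint latent quality
#'
#' All three parameters at the centre of their observed ranges; the zero-effect
#' reference point of the forward model.
#' @param storage_group storage group, default 0.
#' @return `latent_quality`.
#' @export
latent_midpoint <- function(storage_group = 0L) {
  r <- .quality_ranges
  latent_quality(mean(r$ssc), mean(r$ph), mean(r$vc), storage_group)
}

# Map a latent value to [-1, 1] relative to its observed range.
.latent_z <- function(value, which) {
  r <- .quality_ranges[[which]]
  (value - mean(r)) / (diff(r) / 2)
}

#' Forward-model effect configuration
#'
#' Each quality parameter modulates the depth of Gaussian-in-wavelength
#' absorption components. The fixed baseline carries chlorophyll (~680 nm) and
#' water (~750, ~960 nm) absorption dips present in every fruit spectrum;
#' the per-parameter components tie dip depths and the 750-950 nm plateau
#' level to the latent values: reflectance on the plateau rises with SSC and
#' falls with pH and VC.
#'
#' Amplitudes are in reflectance units per unit latent z-score (latent scaled
#' to [-1, 1] over its observed range); positive amplitude deepens the dip.
#'
#' @return nested list: `baseline` components (center nm, width nm, depth) and
#'   per-latent effect components (center, width, amp).
#' @export
forward_model_config <- function() {
  list(
    baseline = list(
      list(center = 680, width = 25, depth = 0.08),  # chlorophyll
      list(center = 750, width = 20, depth = 0.05),  # water 3rd overtone
      list(center = 960, width = 30, depth = 0.10)   # O-H of water
    ),
    effects = list(
      ssc = list(
        list(center = 680, width = 25, amp = 0.05),   # deeper chlorophyll dip
        list(center = 850, width = 60, amp = -0.06)   # plateau rises with SSC
      ),
      ph = list(
        list(center = 750, width = 20, amp = 0.04),
        list(center = 850, width = 60, amp = 0.05)    # plateau falls with pH
      ),
      vc = list(
        list(center = 960, width = 30, amp = 0.05),
        list(center = 850, width = 60, amp = 0.04)    # plateau falls with VC
      )
    )
  )
}

.gauss <- function(wl, center, width) exp(-(wl - center)^2 / (2 * width^2))

# Smooth sigmoid baseline: low reflectance below 500 nm rising to a
# 750-950 nm plateau, minus the fixed absorption dips.
.baseline_spectrum <- function(wl, cfg) {
  base <- 0.10 + 0.55 / (1 + exp(-(wl - 620) / 40))
  for (cp in cfg$baseline) base <- base - cp$depth * .gauss(wl, cp$center, cp$width)
  base
}

#' Latent quality to reflectance spectrum
#'
#' Deterministic forward model mapping a fruit's quality parameters to a
#' smooth reflectance spectrum in (0, 1): a sigmoid baseline (low in the
#' blue-green, high on the near-infrared plateau) with Gaussian absorption
#' components whose depths are monotone in the latent values.
#'
#' @param q `latent_quality`.
#' @param wavelengths nm vector, ascending, within [374, 1020].
#' @param cfg effect configuration, see [forward_model_config()].
#' @return reflectance vector, one value per wavelength, all in (0, 1).
#' @export
spectral_forward_model <- function(q, wavelengths,
                                   cfg = forward_model_config()) {
  stopifnot(inherits(q, "latent_quality"))
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  if (min(wavelengths) < 374 || max(wavelengths) > 1020)
    stop("wavelengths outside supported range [374, 1020] nm")
  refl <- .baseline_spectrum(wavelengths, cfg)
  z <- c(ssc = .latent_z(q$ssc, "ssc"),
         ph  = .latent_z(q$ph,  "ph"),
         vc  = .latent_z(q$vc,  "vc"))
  for (nm in names(cfg$effects)) {
    for (cp in cfg$effects[[nm]]) {
      refl <- refl - cp$amp * z[[nm]] * .gauss(wavelengths, cp$center, cp$width)
    }
  }
  unname(refl)
}

#' Vitamin C content from the spectrophotometric assay
#'
#' Converts an assay measurement to vitamin C content in g per kg fruit:
#' `C * V / M * 1000`, with `C` the VC concentration of the juice (g/mL, from
#' the absorbance calibration curve), `V` the juice volume (mL) and `M` the
#' fruit mass (g).
#'
#' @param C VC concentration, g/mL, non-negative.
#' @param V juice volume, mL, positive.
#' @param M fruit mass, g, positive.
#' @return VC content in g/kg.
#' @export
vc_content <- function(C, V, M) {
  if (any(C < 0)) stop("C must be non-negative")
  if (any(V <= 0)) stop("V must be positive")
  if (any(M <= 0)) stop("M must be positive")
  C * V / M * 1000
}

#' Scene noise / geometry configuration
#'
#' @param frame spatial frame size in pixels (square).
#' @param roi_axes semi-axes (rows, cols) of the elliptical fruit ROI; the
#'   default ellipse covers about 30 percent of the frame.
#' @param noise_sd additive reflectance noise s.d. per pixel per band.
#' @param scatter_offset_sd s.d. of the per-pixel additive scatter offset a.
#' @param scatter_slope_sd s.d. of the per-pixel multiplicative scatter slope
#'   b around 1; per-pixel reflectance is distorted to `a + b * r`, exactly
#'   the distortion multiplicative scatter correction removes.
#' @param background_reflectance flat background reflectance level (dim in the
#'   red band relative to fruit).
#' @param gradient_frac amplitude of the planted left-to-right linear SSC
#'   gradient across the ROI, as a fraction of the SSC half-range; pH and VC
#'   are spatially constant.
#' @param white_level,dark_level mean digital counts of the white and dark
#'   reference frames.
#' @return list of scene parameters.
#' @export
scene_config <- function(frame = 64L, roi_axes = c(22L, 28L),
                         noise_sd = 0.01,
                         scatter_offset_sd = 0.1, scatter_slope_sd = 0.1,
                         background_reflectance = 0.15,
                         gradient_frac = 0.15,
                         white_level = 4000, dark_level = 100) {
  list(frame = as.integer(frame), roi_axes = as.integer(roi_axes),
       noise_sd = noise_sd,
       scatter_offset_sd = scatter_offset_sd,
       scatter_slope_sd = scatter_slope_sd,
       background_reflectance = background_reflectance,
       gradient_frac = gradient_frac,
       white_level = white_level, dark_level = dark_level)
}

#' Generate one synthetic hyperspectral scene
#'
#' Builds a raw-counts hypercube of a single fruit against a dark background,
#' together with white and dark reference frames and per-pixel ground truth.
#' Inside the elliptical fruit mask each pixel's reflectance comes from the
#' forward model evaluated at that pixel's latent quality (the sample latent
#' plus a planted left-to-right SSC gradient), distorted by a per-pixel affine
#' scatter (`a + b * r`) and additive noise; raw counts are then
#' `dark + (white - dark) * reflectance`. Background pixels are spectrally
#' flat. Reproducible for a fixed seed.
#'
#' @param q `latent_quality` for the fruit.
#' @param noise `scene_config()`.
#' @param seed integer seed.
#' @param cfg forward-model configuration.
#' @return object of class `synthetic_scene`: `raw_cube` (rows x cols x
#'   bands counts array), `white_frame`, `dark_frame` (same shape),
#'   `truth_mask` (logical rows x cols), `truth` (the latent quality),
#'   `truth_maps` (per-pixel ssc/ph/vc matrices, NA outside the mask) and
#'   `wavelengths`.
#' @export
generate_scene <- function(q, noise = scene_config(), seed = 1L,
                           cfg = forward_model_config()) {
  stopifnot(inherits(q, "latent_quality"))
  set.seed(as.integer(seed))
  n <- noise$frame
  wl <- default_wavelengths()
  nb <- length(wl)

  # elliptical ROI centred in the frame
  rc <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  mask <- ((rows - rc) / noise$roi_axes[1])^2 +
          ((cols - rc) / noise$roi_axes[2])^2 <= 1
  idx <- which(mask)
  npix <- length(idx)

  # per-pixel latent truth: planted linear SSC gradient along columns
  half_ssc <- diff(.quality_ranges$ssc) / 2
  col_pos <- (cols[idx] - rc) / noise$roi_axes[2]   # in [-1, 1] across the ROI
  ssc_pix <- q$ssc + noise$gradient_frac * half_ssc * col_pos
  ssc_pix <- pmin(pmax(ssc_pix, .quality_ranges$ssc[1]), .quality_ranges$ssc[2])

  truth_maps <- list(
    ssc = matrix(NA_real_, n, n), ph = matrix(NA_real_, n, n),
    vc = matrix(NA_real_, n, n))
  truth_maps$ssc[idx] <- ssc_pix
  truth_maps$ph[idx] <- q$ph
  truth_maps$vc[idx] <- q$vc

  # reflectance per ROI pixel: base spectrum for the sample latent, plus the
  # SSC deviation applied through the SSC effect components only
  base <- spectral_forward_model(q, wl, cfg)
  dz <- (ssc_pix - q$ssc) / half_ssc
  ssc_shape <- numeric(nb)
  for (cp in cfg$effects$ssc)
    ssc_shape <- ssc_shape - cp$amp * .gauss(wl, cp$center, cp$width)
  refl <- matrix(base, npix, nb, byrow = TRUE) + outer(dz, ssc_shape)

  # per-pixel affine scatter, constant across bands for a given pixel
  a <- rnorm(npix, 0, noise$scatter_offset_sd)
  b <- rnorm(npix, 1, noise$scatter_slope_sd)
  refl <- a + b * refl
  if (noise$noise_sd > 0)
    refl <- refl + matrix(rnorm(npix * nb, 0, noise$noise_sd), npix, nb)

  white <- array(noise$white_level, dim = c(n, n, nb))
  dark <- array(noise$dark_level, dim = c(n, n, nb))
  gain <- noise$white_level - noise$dark_level

  raw <- array(noise$dark_level + gain * noise$background_reflectance,
               dim = c(n, n, nb))
  # band-sliced fill of ROI pixels
  for (k in seq_len(nb)) raw[idx + (k - 1) * n * n] <- noise$dark_level + gain * refl[, k]

  structure(list(raw_cube = raw, white_frame = white, dark_frame = dark,
                 truth_mask = mask, truth = q, truth_maps = truth_maps,
                 wavelengths = wl, config = noise, seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' Storage-drift group means
#'
#' Group-mean offsets of the three latents across the five storage times, in
#' units of each latent's half-range: SSC first rises (carbohydrate
#' hydrolysis) then falls (respiration), while pH and VC decline throughout
#' storage.
#' @return list of numeric length-5 offset vectors.
#' @export
storage_drift <- function() {
  list(ssc = c(-0.45, 0.10, 0.50, 0.25, -0.20),
       ph  = c(0.50, 0.25, 0.00, -0.25, -0.50),
       vc  = c(0.50, 0.30, 0.05, -0.20, -0.45))
}

# Truncated-normal draw inside [lo, hi] by rejection.
.rtrunc <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Draw the latent quality table for a storage experiment
#'
#' @param n total samples, divisible by `groups`.
#' @param groups number of storage-time groups.
#' @param seed integer seed.
#' @param within_sd within-group s.d. in units of each latent's half-range.
#' @return data.frame with columns id, group (0-based), ssc, ph, vc.
#' @export
generate_truth <- function(n = 120L, groups = 5L, seed = 1L, within_sd = 0.25) {
  if (n %% groups != 0) stop("n must be divisible by groups")
  set.seed(as.integer(seed))
  per <- n %/% groups
  drift <- storage_drift()
  rows <- lapply(seq_len(groups) - 1L, function(g) {
    vals <- lapply(c("ssc", "ph", "vc"), function(p) {
      r <- .quality_ranges[[p]]
      h <- diff(r) / 2
      off <- drift[[p]][(g %% 5L) + 1L]
      .rtrunc(per, mean(r) + off * h, within_sd * h, r[1], r[2])
    })
    data.frame(id = sprintf("S%03d", g * per + seq_len(per)),
               group = g, ssc = vals[[1]], ph = vals[[2]], vc = vals[[3]])
  })
  do.call(rbind, rows)
}

#' Generate a full synthetic dataset
#'
#' Draws `n` latent quality values in `groups` storage-time groups with the
#' storage drift of [storage_drift()], then renders one scene per sample.
#' With `keep_scenes = FALSE` each scene is processed immediately (calibrated,
#' segmented, ROI-mean spectrum and optionally image features extracted) and
#' discarded, so the full 120-sample experiment fits in memory.
#'
#' @param n samples; must be divisible by `groups`.
#' @param groups storage-time groups.
#' @param seed integer seed; per-scene seeds are derived from it.
#' @param noise `scene_config()`.
#' @param keep_scenes keep the raw scenes in the result?
#' @param extract also extract the ROI-mean spectra (and, if
#'   `extract_images`, color/texture features) per scene?
#' @param extract_images extract color moments and the three per-target
#'   texture blocks (slower)?
#' @param cfg forward-model configuration.
#' @return list with `truth` (data.frame), and depending on flags: `scenes`
#'   (list of `synthetic_scene`), `spectra` (a [spectra_table()] of ROI-mean
#'   calibrated spectra on the full grid), `color` (n x 9 matrix), `texture`
#'   (list of n x 36 matrices, one per target).
#' @export
generate_dataset <- function(n = 120L, groups = 5L, seed = 1L,
                             noise = scene_config(), keep_scenes = FALSE,
                             extract = TRUE, extract_images = FALSE,
                             cfg = forward_model_config()) {
  truth <- generate_truth(n, groups, seed)
  # derived per-scene seeds, kept within 32-bit range
  scene_seeds <- (as.integer(seed) + 7919L * seq_len(n)) %% 2147483647L
  wl <- default_wavelengths()
  scenes <- if (keep_scenes) vector("list", n) else NULL
  spectra <- if (extract) matrix(NA_real_, n, length(wl)) else NULL
  color <- if (extract_images) matrix(NA_real_, n, 9) else NULL
  texture <- if (extract_images)
    lapply(texture_band_pairs(), function(bp) matrix(NA_real_, n, 36)) else NULL

  for (i in seq_len(n)) {
    q <- latent_quality(truth$ssc[i], truth$ph[i], truth$vc[i], truth$group[i])
    sc <- generate_scene(q, noise, scene_seeds[i], cfg)
    if (keep_scenes) scenes[[i]] <- sc
    if (extract || extract_images) {
      cube <- calibrate(as_hypercube(sc), reference_frames(sc))
      mask <- segment_superred(cube)
      if (extract) spectra[i, ] <- mean_spectrum(cube, mask)
      if (extract_images) {
        color[i, ] <- color_moments(cube, mask)
        for (tg in names(texture)) {
          texture[[tg]][i, ] <- texture_block(cube, mask,
                                              texture_band_pairs()[[tg]])
        }
      }
    }
  }
  out <- list(truth = truth, seed = as.integer(seed), noise = noise)
  if (keep_scenes) out$scenes <- scenes
  if (extract)
    out$spectra <- spectra_table(spectra, wl, ids = truth$id)
  if (extract_images) {
    rownames(color) <- truth$id
    out$color <- color
    out$texture <- texture
  }
  out
}

#' @export
print.synthetic_scene <- function(x, ...) {
  d <- dim(x$raw_cube)
  cat(sprintf("synthetic_scene: %d x %d px, %d bands (%.1f-%.1f nm), %d ROI px\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              sum(x$truth_mask)))
  cat(sprintf("  truth: SSC %.2f%%, pH %.2f, VC %.3f g/kg, group %d\n",
              x$truth$ssc, x$truth$ph, x$truth$vc, x$truth$storage_group))
  invisible(x)
}
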