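# Hypercube container, reflectance calibration, fruit segmentation and
# spectrum extraction.

#' Hypercube container
#'
#' A 3-D image (rows x cols x bands) with its wavelength vector and a kind
#' tag distinguishing raw digital counts from calibrated reflectance.
#'
#' @param data numeric rows x cols x bands array.
#' @param wavelengths nm vector, strictly increasing, length = bands.
#' @param kind `"raw"` or `"reflectance"`.
#' @return object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3) stop("data must be a rows x cols x bands array")
  if (dim(data)[3] != length(wavelengths))
    stop("bands dimension must equal wavelength length")
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly increasing")
  structure(list(data = data, wavelengths = as.numeric(wavelengths),
                 kind = kind), class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("hypercube [%s]: %d x %d px, %d bands (%.1f-%.1f nm)\n",
              x$kind, d[1], d[2], d[3],
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' White/dark reference frames
#'
#' @param white counts array, same shape as the cube it calibrates.
#' @param dark counts array, same shape.
#' @return object of class `reference_frames`.
#' @export
reference_frames <- function(white, dark) {
  if (inherits(white, "synthetic_scene")) {
    sc <- white
    return(reference_frames(sc$white_frame, sc$dark_frame))
  }
  if (!identical(dim(white), dim(dark)))
    stop("white and dark frames must have identical shape")
  structure(list(white = white, dark = dark), class = "reference_frames")
}

#' Raw hypercube view of a synthetic scene
#' @param scene `synthetic_scene`.
#' @return raw `hypercube`.
#' @export
as_hypercube <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  hypercube(scene$raw_cube, scene$wavelengths, "raw")
}

#' Reflectance calibration against white/dark references
#'
#' Standard flat-field correction `R = (R_raw - R_d) / (R_w - R_d)` removing
#' uneven illumination and camera dark current: element-wise over the cube.
#'
#' @param raw raw-kind `hypercube`.
#' @param refs `reference_frames` with the cube's shape.
#' @return reflectance-kind `hypercube`.
#' @export
calibrate <- function(raw, refs) {
  stopifnot(inherits(raw, "hypercube"), inherits(refs, "reference_frames"))
  if (raw$kind != "raw") stop("cube is already calibrated")
  if (!identical(dim(raw$data), dim(refs$white)))
    stop("reference frame shape does not match the cube")
  denom <- refs$white - refs$dark
  bad <- which(denom == 0)
  if (length(bad))
    stop(sprintf("white == dark at %d element(s), first at linear index %d",
                 length(bad), bad[1]))
  hypercube((raw$data - refs$dark) / denom, raw$wavelengths, "reflectance")
}

#' Crop a hypercube to a wavelength window
#'
#' Keeps bands with `lo <= wavelength <= hi` (closed interval at both ends);
#' the canonical use is restricting to the low-noise 400-1000 nm region.
#'
#' @param cube `hypercube` or `spectra_table`.
#' @param lo,hi window bounds in nm, `lo < hi`.
#' @return same class as the input, with the band subset.
#' @export
crop_bands <- function(cube, lo = 400, hi = 1000) {
  if (lo >= hi) stop("lo must be < hi")
  keep <- cube$wavelengths >= lo & cube$wavelengths <= hi
  if (!any(keep)) stop("no bands inside the requested window")
  if (inherits(cube, "spectra_table")) {
    return(spectra_table(cube$X[, keep, drop = FALSE], cube$wavelengths[keep],
                         ids = cube$ids, pretreatment = cube$pretreatment))
  }
  stopifnot(inherits(cube, "hypercube"))
  hypercube(cube$data[, , keep, drop = FALSE], cube$wavelengths[keep],
            cube$kind)
}

#' Single-band image
#' @param cube reflectance `hypercube`.
#' @param wavelength requested wavelength (nm), nearest-band rule.
#' @return numeric matrix.
#' @export
band_image <- function(cube, wavelength) {
  stopifnot(inherits(cube, "hypercube"))
  cube$data[, , resolve_bands(cube$wavelengths, wavelength)]
}

# Otsu's threshold on a numeric image (256-bin histogram between min and max).
.otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(as.integer((x - rng[1]) / diff(rng) * n_bins) + 1L,
                     n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / n_bins * diff(rng)
}

# Largest 4-connected component of a logical matrix, by iterative frontier
# expansion.
.largest_component <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  current <- 0L
  todo <- which(mask)
  for (s in todo) {
    if (lab[s] != 0L) next
    current <- current + 1L
    frontier <- s
    lab[s] <- current
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      cc <- (frontier - 1L) %/% nr + 1L
      nb <- c(frontier[r > 1L] - 1L, frontier[r < nr] + 1L,
              frontier[cc > 1L] - nr, frontier[cc < nc] + nr)
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- current
      frontier <- nb
    }
  }
  if (current == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L], current)
  lab == which.max(sizes)
}

#' Segment the fruit by its super-red characteristic
#'
#' Thresholds the super-red score image `2R - G - B` built from the band
#' images nearest the requested red/green/blue wavelengths, then keeps the
#' largest 4-connected component to drop background specks. The default
#' threshold is Otsu's method on the score image.
#'
#' @param cube reflectance `hypercube`.
#' @param rgb_wavelengths red, green, blue band centres in nm.
#' @param threshold numeric score threshold, or `"otsu"`.
#' @return object of class `roi_mask`: logical matrix plus `pixel_count`.
#' @export
segment_superred <- function(cube, rgb_wavelengths = c(691, 531, 457),
                             threshold = "otsu") {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$kind != "reflectance") stop("segment a calibrated cube")
  ch <- lapply(rgb_wavelengths, function(w) band_image(cube, w))
  score <- 2 * ch[[1]] - ch[[2]] - ch[[3]]
  t <- if (identical(threshold, "otsu")) .otsu_threshold(score) else threshold
  m <- score > t
  if (!any(m)) stop("segmentation produced an empty mask")
  m <- .largest_component(m)
  structure(list(mask = m, pixel_count = sum(m), threshold = t),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask: %d x %d, %d pixels (threshold %.4g)\n",
              nrow(x$mask), ncol(x$mask), x$pixel_count, x$threshold))
  invisible(x)
}

#' ROI-mean spectrum
#'
#' Per-band arithmetic mean of the reflectance over the masked pixels.
#'
#' @param cube reflectance `hypercube`.
#' @param mask `roi_mask` or logical matrix with at least one TRUE pixel.
#' @return numeric vector, one value per band.
#' @export
mean_spectrum <- function(cube, mask) {
  stopifnot(inherits(cube, "hypercube"))
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  idx <- which(m)
  if (!length(idx)) stop("mask is empty")
  d <- dim(cube$data)
  mat <- matrix(cube$data, d[1] * d[2], d[3])
  colMeans(mat[idx, , drop = FALSE])
}

# ---- on-disk formats -------------------------------------------------------

#' Write a hypercube as an ENVI-style header + BSQ binary pair
#'
#' `path` is the basename; `path.hdr` (text header with samples/lines/bands,
#' data type 5 = double, interleave bsq, byte order 0 and the wavelength
#' list) and `path.dat` (band-sequential little-endian doubles) are written.
#'
#' @param cube `hypercube`.
#' @param path output basename (no extension).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           "interleave = bsq",
           "byte order = 0",
           sprintf("kind = %s", cube$kind),
           paste0("wavelength = { ",
                  paste(format(cube$wavelengths, trim = TRUE), collapse = ", "),
                  " }"))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  # BSQ: full band planes in sequence, row-major within a plane
  for (k in seq_len(d[3]))
    writeBin(as.vector(t(cube$data[, , k])), con, size = 8, endian = "little")
  invisible(path)
}

.parse_envi_header <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(txt, regexec(paste0(key, "\\s*=\\s*(\\d+)"), txt))[[1]]
    if (length(m) < 2) stop(sprintf("ENVI header missing '%s'", key))
    as.integer(m[2])
  }
  m <- regmatches(txt, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", txt))[[1]]
  if (length(m) < 2) stop("ENVI header missing wavelength list")
  wl <- as.numeric(strsplit(m[2], ",")[[1]])
  kindm <- regmatches(txt, regexec("kind\\s*=\\s*(\\w+)", txt))[[1]]
  list(samples = get_num("samples"), lines = get_num("lines"),
       bands = get_num("bands"), wavelengths = wl,
       kind = if (length(kindm) >= 2) kindm[2] else "reflectance")
}

#' Read an ENVI-style header + BSQ binary pair
#' @param path basename written by [write_envi()].
#' @return `hypercube`.
#' @export
read_envi <- function(path) {
  h <- .parse_envi_header(readLines(paste0(path, ".hdr")))
  if (length(h$wavelengths) != h$bands)
    stop("ENVI header wavelength count does not match bands")
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  n <- h$lines * h$samples * h$bands
  v <- readBin(con, "double", n, size = 8, endian = "little")
  if (length(v) != n) stop("ENVI data file shorter than header promises")
  cube <- array(NA_real_, c(h$lines, h$samples, h$bands))
  plane <- h$lines * h$samples
  for (k in seq_len(h$bands)) {
    cube[, , k] <- t(matrix(v[(k - 1) * plane + seq_len(plane)],
                            h$samples, h$lines))
  }
  hypercube(cube, h$wavelengths, h$kind)
}

#' Write / read a scene as a compressed array container
#'
#' Portable single-file container (serialized R list, gzip-compressed) for a
#' whole `synthetic_scene` including reference frames and truth.
#' @param scene `synthetic_scene`.
#' @param path file path.
#' @return `path` / the scene.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "synthetic_scene"))
  saveRDS(scene, path, compress = "gzip")
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  sc <- readRDS(path)
  stopifnot(inherits(sc, "synthetic_scene"))
  sc
}

#' Write a mask as a black/white PNG for inspection
#' @param mask `roi_mask` or logical matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  png::writePNG(m * 1, path)
  invisible(path)
}
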