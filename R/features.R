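# Image features inside the fruit ROI: color moments, gray level-gradient
# co-occurrence matrix (GLGCM) statistics and Gabor filter statistics.

#' Color moments of the ROI
#'
#' First three moments of the pixel intensity distribution of the red, green
#' and blue band images (reflectance scale, no 8-bit quantization), restricted
#' to the mask: mean, population standard deviation, and the signed cube root
#' of the third central moment (skew on the intensity scale). Nine features,
#' ordered (R1, R2, R3, G1, G2, G3, B1, B2, B3).
#'
#' @param cube reflectance `hypercube`.
#' @param mask `roi_mask` or logical matrix, nonempty.
#' @param rgb_wavelengths red, green, blue band centres (nm).
#' @return named numeric vector of length 9.
#' @export
color_moments <- function(cube, mask, rgb_wavelengths = c(691, 531, 457)) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!any(m)) stop("mask is empty")
  out <- unlist(lapply(seq_along(rgb_wavelengths), function(i) {
    px <- band_image(cube, rgb_wavelengths[i])[m]
    mu <- mean(px)
    v <- mean((px - mu)^2)
    m3 <- mean((px - mu)^3)
    c(mu, sqrt(v), sign(m3) * abs(m3)^(1 / 3))
  }))
  names(out) <- paste0(rep(c("R", "G", "B"), each = 3), 1:3)
  out
}

#' GLGCM configuration
#'
#' @param gray_levels,grad_levels quantization levels (>= 2) for intensity
#'   and gradient magnitude; both quantized by max-scaling
#'   `round(x * (L - 1) / max)`.
#' @param gradient_operator gradient operator name (only `"sobel"`).
#' @return list.
#' @export
glgcm_config <- function(gray_levels = 16L, grad_levels = 16L,
                         gradient_operator = "sobel") {
  if (gray_levels < 2 || grad_levels < 2) stop("levels must be >= 2")
  list(gray_levels = as.integer(gray_levels),
       grad_levels = as.integer(grad_levels),
       gradient_operator = gradient_operator)
}

#' @export
glgcm_feature_names <- function() {
  c("small_grads_dominance", "big_grads_dominance", "gray_asymmetry",
    "grads_asymmetry", "energy", "gray_mean", "grads_mean", "gray_variance",
    "grads_variance", "correlation", "gray_entropy", "grads_entropy",
    "entropy", "inertia", "homogeneity")
}

# 3x3 Sobel gradient magnitude with edge-replication padding.
.sobel_magnitude <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  p <- img[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]  # replicate edges
  sh <- function(dr, dc) p[dr + seq_len(nr), dc + seq_len(nc)]
  gx <- (sh(0, 2) + 2 * sh(1, 2) + sh(2, 2)) -
        (sh(0, 0) + 2 * sh(1, 0) + sh(2, 0))
  gy <- (sh(2, 0) + 2 * sh(2, 1) + sh(2, 2)) -
        (sh(0, 0) + 2 * sh(0, 1) + sh(0, 2))
  sqrt(gx^2 + gy^2)
}

# max-scaling quantizer to 0..(L-1); all-zero input maps to level 0
.quantize <- function(x, L) {
  mx <- max(x)
  if (mx <= 0) return(rep(0L, length(x)))
  as.integer(round(x * (L - 1) / mx))
}

# The 15 statistics from a normalized joint gray/grad probability table
# p[i, j], indices 1-based. 0 * log 0 taken as 0.
.glgcm_stats <- function(p) {
  L <- nrow(p); K <- ncol(p)
  i <- matrix(seq_len(L), L, K)
  j <- matrix(seq_len(K), L, K, byrow = TRUE)
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  mu_i <- sum(seq_len(L) * pi_)
  mu_j <- sum(seq_len(K) * pj_)
  var_i <- sum((seq_len(L) - mu_i)^2 * pi_)
  var_j <- sum((seq_len(K) - mu_j)^2 * pj_)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  corr <- if (var_i > 0 && var_j > 0)
    sum((i - mu_i) * (j - mu_j) * p) / sqrt(var_i * var_j) else 0
  c(small_grads_dominance = sum(p / j^2),
    big_grads_dominance = sum(p * j^2),
    gray_asymmetry = sum(pi_^2),
    grads_asymmetry = sum(pj_^2),
    energy = sum(p^2),
    gray_mean = mu_i,
    grads_mean = mu_j,
    gray_variance = var_i,
    grads_variance = var_j,
    correlation = corr,
    gray_entropy = ent(pi_),
    grads_entropy = ent(pj_),
    entropy = ent(p),
    inertia = sum((i - j)^2 * p),
    homogeneity = sum(p / (1 + (i - j)^2)))
}

#' Gray level-gradient co-occurrence matrix features
#'
#' Computes the Sobel gradient magnitude over the mask's bounding-box crop
#' (background filled by edge replication), quantizes intensity and gradient
#' to the configured levels by max-scaling, accumulates the joint histogram
#' over masked pixels, normalizes it to probabilities and returns 15 texture
#' statistics: small/big grads dominance, gray/grads asymmetry (energy of the
#' marginals), energy, gray/grads mean, gray/grads variance, correlation,
#' gray/grads entropy, mixed entropy, inertia and homogeneity (entropies in
#' bits; a degenerate zero-variance correlation is defined as 0).
#'
#' @param image numeric band image (matrix).
#' @param mask `roi_mask` or logical matrix; bounding box at least 3 x 3.
#' @param cfg [glgcm_config()].
#' @return named numeric vector of length 15.
#' @export
glgcm_features <- function(image, mask = NULL, cfg = glgcm_config()) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else
    if (is.null(mask)) matrix(TRUE, nrow(image), ncol(image)) else mask
  if (!any(m)) stop("mask is empty")
  rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
  if (diff(rr) < 2 || diff(cc) < 2) stop("mask bounding box must be >= 3 x 3")
  img <- image[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  sub <- m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  # outside-mask pixels replaced by the nearest masked value along rows
  # (then cols) so the Sobel response at ROI-edge pixels is not driven by
  # background; features stay invariant to anything outside the mask.
  img <- .fill_background(img, sub)
  grad <- .sobel_magnitude(img)
  gq <- .quantize(img[sub], cfg$gray_levels) + 1L
  dq <- .quantize(grad[sub], cfg$grad_levels) + 1L
  H <- matrix(tabulate((dq - 1L) * cfg$gray_levels + gq,
                       cfg$gray_levels * cfg$grad_levels),
              cfg$gray_levels, cfg$grad_levels)
  .glgcm_stats(H / sum(H))
}

# Replace background pixels by the nearest masked pixel value (grassfire-ish:
# repeated 4-neighbour dilation of known values until the crop is filled).
.fill_background <- function(img, mask) {
  if (all(mask)) return(img)
  known <- mask
  out <- img
  out[!mask] <- NA_real_
  nr <- nrow(out); nc <- ncol(out)
  while (any(!known)) {
    shifted <- list(
      rbind(out[1, , drop = FALSE], out[-nr, , drop = FALSE]),
      rbind(out[-1, , drop = FALSE], out[nr, , drop = FALSE]),
      cbind(out[, 1, drop = FALSE], out[, -nc, drop = FALSE]),
      cbind(out[, -1, drop = FALSE], out[, nc, drop = FALSE]))
    cand <- Reduce(function(a, b) ifelse(is.na(a), b, a), shifted)
    fill <- !known & !is.na(cand)
    if (!any(fill)) break  # isolated region; fill with the masked mean
    out[fill] <- cand[fill]
    known <- known | fill
  }
  if (any(!known)) out[!known] <- mean(img[mask])
  out
}

#' Gabor filter kernel
#'
#' Complex Gabor: Gaussian envelope with semi-axes `sigma` (x along the
#' modulation direction, y across it) modulated by a plane wave of spatial
#' frequency `freq` at orientation `theta`. The kernel is made exactly
#' zero-DC by subtracting the envelope scaled to cancel the kernel sum, so a
#' constant image yields zero response.
#'
#' @param sigma envelope semi-axes (x, y) in pixels.
#' @param theta orientation in degrees.
#' @param freq modulation frequency, cycles per pixel.
#' @return complex matrix kernel.
#' @export
gabor_kernel <- function(sigma = c(2, 4), theta = 60, freq = 0.25) {
  half <- ceiling(3 * max(sigma))
  xs <- -half:half
  x <- matrix(xs, length(xs), length(xs), byrow = TRUE)   # column index
  y <- matrix(xs, length(xs), length(xs))                 # row index
  th <- theta * pi / 180
  xr <- x * cos(th) + y * sin(th)
  yr <- -x * sin(th) + y * cos(th)
  env <- exp(-(xr^2 / (2 * sigma[1]^2) + yr^2 / (2 * sigma[2]^2)))
  g <- env * exp(2i * pi * freq * xr)
  g - env * (sum(g) / sum(env))   # exact zero DC gain
}

# 'same' 2-D convolution (correlation with a conjugate-symmetric use is not
# needed; Gabor statistics use the magnitude) via FFT with zero padding.
.conv2_same <- function(img, ker) {
  nr <- nrow(img) + nrow(ker) - 1
  nc <- ncol(img) + ncol(ker) - 1
  pad <- function(m) {
    out <- matrix(0 + 0i, nr, nc)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  full <- stats::fft(stats::fft(pad(img)) * stats::fft(pad(ker)),
                     inverse = TRUE) / (nr * nc)
  r0 <- (nrow(ker) - 1) %/% 2
  c0 <- (ncol(ker) - 1) %/% 2
  full[r0 + seq_len(nrow(img)), c0 + seq_len(ncol(img))]
}

#' Gabor texture features of the ROI
#'
#' Convolves the mask's bounding-box crop (edge-replicated background) with
#' the configured Gabor kernel and summarizes the response magnitude over
#' the masked pixels by its mean, contrast (population standard deviation)
#' and the entropy (bits) of its 64-bin histogram.
#'
#' @param image numeric band image.
#' @param mask `roi_mask` or logical matrix.
#' @param sigma envelope semi-axes (x, y); the texture scale.
#' @param theta orientation in degrees.
#' @param freq modulation frequency in cycles/pixel.
#' @return named numeric vector of length 3: mean, contrast, entropy.
#' @export
gabor_features <- function(image, mask = NULL, sigma = c(2, 4), theta = 60,
                           freq = 0.25) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else
    if (is.null(mask)) matrix(TRUE, nrow(image), ncol(image)) else mask
  if (!any(m)) stop("mask is empty")
  ker <- gabor_kernel(sigma, theta, freq)
  rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
  img <- .fill_background(image[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE],
                          m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE])
  if (nrow(ker) > nrow(img) || ncol(ker) > ncol(img))
    stop("kernel larger than the mask bounding box")
  # replicate edges outward by the kernel half-size before convolving
  hr <- (nrow(ker) - 1) %/% 2
  padded <- img[c(rep(1, hr), seq_len(nrow(img)), rep(nrow(img), hr)),
                c(rep(1, hr), seq_len(ncol(img)), rep(ncol(img), hr)),
                drop = FALSE]
  resp <- Mod(.conv2_same(padded, ker))
  resp <- resp[hr + seq_len(nrow(img)), hr + seq_len(ncol(img)), drop = FALSE]
  v <- resp[m[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]]
  mu <- mean(v)
  contrast <- sqrt(mean((v - mu)^2))
  rngv <- range(v)
  h <- if (diff(rngv) == 0) c(length(v), rep(0, 63)) else
    tabulate(pmin(as.integer((v - rngv[1]) / diff(rngv) * 64) + 1L, 64L), 64L)
  p <- h / sum(h); p <- p[p > 0]
  c(gabor_mean = mu, gabor_contrast = contrast, gabor_entropy = -sum(p * log2(p)))
}

#' Texture band pairs per quality parameter
#'
#' The two wavelengths whose band images carry the texture information for
#' each target (selected by CARS band weighting on the reference study's
#' spectra): 676/910 nm for SSC, 444/842 nm for pH, 837/891 nm for VC.
#' @return named list of length-2 nm vectors.
#' @export
texture_band_pairs <- function() {
  list(ssc = c(676, 910), ph = c(444, 842), vc = c(837, 891))
}

#' Full texture block at a pair of wavelengths
#'
#' Concatenates, for each of the two band images, the 15 GLGCM statistics
#' and the 3 Gabor statistics: 36 features total, ordered
#' (GLGCM at band 1, Gabor at band 1, GLGCM at band 2, Gabor at band 2).
#'
#' @param cube reflectance `hypercube`.
#' @param mask `roi_mask`.
#' @param band_pair two wavelengths in nm.
#' @param cfg [glgcm_config()].
#' @return named numeric vector of length 36.
#' @export
texture_block <- function(cube, mask, band_pair, cfg = glgcm_config()) {
  stopifnot(length(band_pair) == 2)
  out <- unlist(lapply(seq_along(band_pair), function(k) {
    img <- band_image(cube, band_pair[k])
    v <- c(glgcm_features(img, mask, cfg), gabor_features(img, mask))
    names(v) <- paste0(names(v), "_", format(band_pair[k], trim = TRUE), "nm")
    v
  }))
  out
}

#' Assemble a fused feature table
#'
#' Horizontal concatenation of the requested blocks in the order spectral,
#' color, texture, with per-feature block tags recorded for reporting and
#' selection bookkeeping.
#'
#' @param spectra `spectra_table`.
#' @param color optional samples x 9 matrix of color moments.
#' @param texture optional samples x 36 matrix of texture features.
#' @param include character subset of `c("spectral", "color", "texture")`.
#' @return object of class `feature_table`: matrix `F`, `names`, `blocks`,
#'   `ids`, and `wavelengths` aligned with the spectral columns.
#' @export
assemble_features <- function(spectra, color = NULL, texture = NULL,
                              include = c("spectral", "color", "texture")) {
  include <- match.arg(include, several.ok = TRUE)
  stopifnot(inherits(spectra, "spectra_table"))
  parts <- list(); blocks <- character(0); wl <- numeric(0)
  if ("spectral" %in% include) {
    M <- spectra$X
    colnames(M) <- paste0("wl", format(spectra$wavelengths, trim = TRUE))
    parts <- c(parts, list(M))
    blocks <- c(blocks, rep("spectral", ncol(M)))
    wl <- c(wl, spectra$wavelengths)
  }
  for (blk in c("color", "texture")) {
    if (!blk %in% include) next
    M <- switch(blk, color = color, texture = texture)
    if (is.null(M)) stop(sprintf("block '%s' requested but not supplied", blk))
    M <- as.matrix(M)
    expected <- switch(blk, color = 9L, texture = 36L)
    if (ncol(M) != expected)
      stop(sprintf("%s block must have %d columns", blk, expected))
    if (nrow(M) != nrow(spectra$X)) stop("block row counts must agree")
    if (!is.null(rownames(M)) && !identical(rownames(M), spectra$ids))
      stop("sample ids of blocks do not align")
    parts <- c(parts, list(M))
    blocks <- c(blocks, rep(blk, ncol(M)))
    wl <- c(wl, rep(NA_real_, ncol(M)))
  }
  F <- do.call(cbind, parts)
  rownames(F) <- spectra$ids
  structure(list(F = F, names = colnames(F), blocks = blocks,
                 ids = spectra$ids, wavelengths = wl),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features (%s)\n",
              nrow(x$F), ncol(x$F),
              paste(sprintf("%s=%d", names(table(x$blocks)),
                            table(x$blocks)), collapse = ", ")))
  invisible(x)
}

#' Feature table CSV round-trip (two-row header: block tag, feature name)
#' @param table `feature_table`.
#' @param path file path.
#' @return `path` / the table.
#' @export
write_features_csv <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("block", table$blocks), collapse = ","), con)
  writeLines(paste(c("id", table$names), collapse = ","), con)
  utils::write.table(data.frame(table$ids, table$F), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  blocks <- strsplit(readLines(path, n = 1), ",")[[1]][-1]
  df <- utils::read.csv(path, skip = 1, check.names = FALSE)
  F <- as.matrix(df[, -1, drop = FALSE])
  rownames(F) <- df[[1]]
  wl <- ifelse(blocks == "spectral",
               suppressWarnings(as.numeric(sub("^wl", "", colnames(F)))),
               NA_real_)
  structure(list(F = F, names = colnames(F), blocks = blocks,
                 ids = as.character(df[[1]]), wavelengths = wl),
            class = "feature_table")
}
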