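# Spectra container and row-wise pretreatments: multiplicative scatter
# correction and wavelet denoising.

#' Spectra table
#'
#' Samples x bands matrix of ROI-mean reflectance, with wavelengths, sample
#' ids and a pretreatment tag.
#'
#' @param X numeric samples x bands matrix.
#' @param wavelengths nm vector, length = columns of X.
#' @param ids sample labels, length = rows of X.
#' @param pretreatment `"none"`, `"wt"` or `"msc"`.
#' @return object of class `spectra_table`.
#' @export
spectra_table <- function(X, wavelengths, ids = NULL,
                          pretreatment = c("none", "wt", "msc")) {
  pretreatment <- match.arg(pretreatment)
  X <- as.matrix(X)
  if (ncol(X) != length(wavelengths))
    stop("column count must equal wavelength count")
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(X)))
  if (length(ids) != nrow(X)) stop("row count must equal id count")
  rownames(X) <- ids
  structure(list(X = X, wavelengths = as.numeric(wavelengths),
                 ids = as.character(ids), pretreatment = pretreatment),
            class = "spectra_table")
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("spectra_table: %d samples x %d bands (%.1f-%.1f nm), pretreatment %s\n",
              nrow(x$X), ncol(x$X), min(x$wavelengths), max(x$wavelengths),
              x$pretreatment))
  invisible(x)
}

#' Multiplicative scatter correction
#'
#' Removes per-spectrum additive/multiplicative scatter: each row `x` is
#' regressed on a reference spectrum `m` by least squares, `x = a + b m`,
#' and replaced by `(x - a) / b`. The reference defaults to the column mean
#' of the rows being corrected; for prediction-set rows, pass the reference
#' frozen from the calibration set to avoid leakage across the split.
#'
#' @param table `spectra_table`.
#' @param reference band vector of the reference spectrum, or `"mean"`.
#' @return corrected `spectra_table` (tag `msc`) with the reference stored in
#'   attribute `"msc_reference"`.
#' @export
msc <- function(table, reference = "mean") {
  stopifnot(inherits(table, "spectra_table"))
  X <- table$X
  if (ncol(X) < 2) stop("MSC needs at least 2 bands")
  m <- if (identical(reference, "mean")) colMeans(X) else as.numeric(reference)
  if (length(m) != ncol(X)) stop("reference length must equal band count")
  mc <- m - mean(m)
  denom <- sum(mc^2)
  out <- X
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    b <- sum((x - mean(x)) * mc) / denom
    if (abs(b) < 1e-12)
      stop(sprintf("degenerate spectrum in row %d: zero slope against reference", i))
    a <- mean(x) - b * mean(m)
    out[i, ] <- (x - a) / b
  }
  res <- spectra_table(out, table$wavelengths, table$ids, "msc")
  attr(res, "msc_reference") <- m
  res
}

# ---- periodized orthonormal discrete wavelet transform ---------------------

# Daubechies-4 (8-tap) scaling filter, frozen at full double precision.
.db4_rec_lo <- c(0.23037781330889651, 0.71484657055291567,
                 0.63088076792985892, -0.027983769416859854,
                 -0.18703481171909309, 0.030841381835560764,
                 0.032883011666885197, -0.010597401785069032)

# One-level orthonormal analysis matrix (N x N, N even) for the periodized
# DWT: first N/2 rows are even shifts of the scaling filter, last N/2 rows
# even shifts of the wavelet filter. Orthonormal, so synthesis is t(W).
.dwt_matrix <- function(n) {
  g <- .db4_rec_lo
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1)   # quadrature mirror wavelet filter
  half <- n / 2
  W <- matrix(0, n, n)
  for (k in seq_len(half)) {
    pos <- ((2 * (k - 1) + seq_len(L) - 1) %% n) + 1
    for (j in seq_len(L)) {
      W[k, pos[j]] <- W[k, pos[j]] + g[j]
      W[half + k, pos[j]] <- W[half + k, pos[j]] + h[j]
    }
  }
  W
}

# Multi-level periodized DWT of the rows of X (ncol divisible by 2^level).
# Returns list(coef = matrix of stacked [approx | details...], slots =
# index list per level, W = per-level matrices for reconstruction).
.dwt_rows <- function(X, level) {
  n <- ncol(X)
  if (n %% 2^level != 0) stop("band count must be divisible by 2^level")
  Ws <- list()
  approx <- X
  details <- list()
  for (l in seq_len(level)) {
    W <- .dwt_matrix(ncol(approx))
    Ws[[l]] <- W
    co <- approx %*% t(W)
    half <- ncol(approx) / 2
    approx <- co[, seq_len(half), drop = FALSE]
    details[[l]] <- co[, half + seq_len(half), drop = FALSE]
  }
  list(approx = approx, details = details, W = Ws)
}

.idwt_rows <- function(dec) {
  approx <- dec$approx
  for (l in rev(seq_along(dec$details))) {
    co <- cbind(approx, dec$details[[l]])
    approx <- co %*% dec$W[[l]]
  }
  approx
}

#' Wavelet denoising of spectra
#'
#' Per-row orthonormal Daubechies wavelet decomposition (periodized, with
#' symmetric-reflection padding up to a length divisible by `2^level`),
#' thresholding of the detail coefficients, and reconstruction to the
#' original band count. The default rule is the soft universal threshold
#' `sigma * sqrt(2 log n)` with the noise scale `sigma` estimated per row
#' from the median absolute finest-level detail / 0.6745.
#'
#' @param table `spectra_table`.
#' @param level decomposition depth; band count (after padding) must be at
#'   least `2^level`.
#' @param rule `"soft"` (shrink) or `"hard"` (keep-or-kill).
#' @param threshold fixed numeric threshold, or `NULL` for the universal rule.
#' @return denoised `spectra_table` (tag `wt`).
#' @export
wt_denoise <- function(table, level = 3L, rule = c("soft", "hard"),
                       threshold = NULL) {
  stopifnot(inherits(table, "spectra_table"))
  rule <- match.arg(rule)
  n <- ncol(table$X)
  if (n < 2^level) stop("level too deep for the band count")
  block <- 2^level
  pad <- (block - n %% block) %% block
  Xp <- if (pad > 0) {
    # reflect the tail so the padded signal stays smooth
    cbind(table$X, table$X[, n - seq_len(pad), drop = FALSE])
  } else table$X
  dec <- .dwt_rows(Xp, level)
  finest <- dec$details[[1]]
  sigma <- apply(abs(finest), 1, stats::median) / 0.6745
  thr <- if (is.null(threshold)) sigma * sqrt(2 * log(ncol(Xp))) else
    rep(threshold, nrow(Xp))
  for (l in seq_along(dec$details)) {
    D <- dec$details[[l]]
    if (rule == "soft") {
      D <- sign(D) * pmax(abs(D) - thr, 0)
    } else {
      D[abs(D) < thr] <- 0
    }
    dec$details[[l]] <- D
  }
  out <- .idwt_rows(dec)[, seq_len(n), drop = FALSE]
  spectra_table(out, table$wavelengths, table$ids, "wt")
}

#' Apply a named pretreatment
#'
#' Convenience dispatcher used by the experiment driver. For `"msc"` the
#' reference is fit on the calibration rows only and reused for the rest.
#'
#' @param table `spectra_table`.
#' @param method `"none"`, `"wt"` or `"msc"`.
#' @param calibration_ids ids defining the rows the MSC reference is computed
#'   from; default all rows.
#' @return pretreated `spectra_table`.
#' @export
pretreat <- function(table, method = c("none", "wt", "msc"),
                     calibration_ids = NULL) {
  method <- match.arg(method)
  switch(method,
    none = table,
    wt = wt_denoise(table),
    msc = {
      ref <- if (is.null(calibration_ids)) colMeans(table$X) else
        colMeans(table$X[table$ids %in% calibration_ids, , drop = FALSE])
      msc(table, ref)
    })
}

#' Spectra table CSV round-trip
#'
#' First column `id`, then one column per band named by its wavelength.
#' @param table `spectra_table`.
#' @param path file path.
#' @return `path` / the table.
#' @export
write_spectra_csv <- function(table, path) {
  stopifnot(inherits(table, "spectra_table"))
  df <- data.frame(id = table$ids, table$X, check.names = FALSE)
  colnames(df) <- c("id", format(table$wavelengths, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  wl <- as.numeric(colnames(df)[-1])
  X <- as.matrix(df[, -1, drop = FALSE])
  dimnames(X) <- NULL
  spectra_table(X, wl, ids = df$id)
}
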