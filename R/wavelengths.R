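#' Default spectrograph wavelength grid
#'
#' The pipeline's native band grid: 280 bands starting at 374 nm with a
#' 2.31 nm step, covering roughly 374-1020 nm, the working range of a
#' visible/near-infrared pushbroom spectrograph.
#'
#' @param n_bands number of bands.
#' @param start first wavelength in nm.
#' @param step band spacing in nm.
#' @return numeric vector of wavelengths (nm), strictly increasing.
#' @export
default_wavelengths <- function(n_bands = 280L, start = 374, step = 2.31) {
  start + step * (seq_len(n_bands) - 1)
}

#' Resolve requested wavelengths to band indices
#'
#' Nearest-band rule; ties broken toward the lower band. Wavelengths are the
#' public addressing scheme, band indices are internal.
#'
#' @param wavelengths grid of band centres (nm), strictly increasing.
#' @param targets requested wavelengths (nm).
#' @return integer band indices, same length as `targets`.
#' @export
resolve_bands <- function(wavelengths, targets) {
  stopifnot(is.numeric(wavelengths), !is.unsorted(wavelengths, strictly = TRUE))
  vapply(targets, function(t) {
    d <- abs(wavelengths - t)
    # which.min returns the first (lower) index on ties
    which.min(d)
  }, integer(1))
}
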