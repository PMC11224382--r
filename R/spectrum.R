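#' Default wavelength grid
#'
#' The hyperspectral camera samples 462 reflectance bands spanning
#' 386--1004 nm; the grid is taken as linearly spaced over that range
#' (spacing about 1.34 nm), which is the only spacing consistent with the
#' band count.
#'
#' @param n_bands number of bands.
#' @param range numeric length-2, wavelength range in nm.
#' @return numeric vector of wavelengths in nm, strictly increasing.
#' @export
default_wavelengths <- function(n_bands = 462L, range = c(386, 1004)) {
  stopifnot(n_bands >= 2L, length(range) == 2L, range[2] > range[1])
  seq(range[1], range[2], length.out = n_bands)
}

#' Construct a reflectance spectrum
#'
#' A spectrum pairs a strictly increasing wavelength grid (nm) with a
#' reflectance vector of the same length.
#'
#' @param reflectance numeric vector of unitless reflectance values.
#' @param wavelengths numeric vector of wavelengths in nm; defaults to the
#'   standard 386--1004 nm grid of matching length.
#' @return an object of class `"spectrum"`: a list with elements
#'   `wavelengths` and `reflectance`.
#' @export
spectrum <- function(reflectance,
                     wavelengths = default_wavelengths(length(reflectance))) {
  reflectance <- as.numeric(reflectance)
  wavelengths <- as.numeric(wavelengths)
  if (length(reflectance) != length(wavelengths))
    stop("wavelengths and reflectance must have equal length")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(reflectance)))
    stop("reflectance must be finite")
  structure(list(wavelengths = wavelengths, reflectance = reflectance),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %d bands, %.1f-%.1f nm, reflectance [%.4g, %.4g]>\n",
              length(x$reflectance), min(x$wavelengths), max(x$wavelengths),
              min(x$reflectance), max(x$reflectance)))
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$reflectance)

# Accept either a spectrum object or a bare numeric vector.
as_reflectance <- function(x) {
  if (inherits(x, "spectrum")) x$reflectance else as.numeric(x)
}
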