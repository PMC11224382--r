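# Spectral preprocessing: ROI-mean extraction, multiplicative scatter
# correction (MSC), min-max normalization, first derivative.

#' Mean spectrum over a region of interest
#'
#' Averages a hyperspectral cube over the pixels of a boolean mask, giving
#' the per-band arithmetic mean reflectance of the region (one spectrum per
#' pod).
#'
#' @param cube numeric array `H x W x B` of reflectance values.
#' @param mask logical matrix `H x W`; `TRUE` marks region-of-interest pixels.
#' @param wavelengths wavelength grid for the `B` bands.
#' @return a [spectrum] of length `B`.
#' @export
roi_mean_spectrum <- function(cube, mask,
                              wavelengths = default_wavelengths(dim(cube)[3])) {
  stopifnot(length(dim(cube)) == 3L)
  mask <- as.matrix(mask)
  if (!identical(dim(cube)[1:2], dim(mask)))
    stop("cube and mask spatial dimensions disagree")
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty ROI: mask selects no pixels")
  b <- dim(cube)[3]
  flat <- matrix(cube, nrow = prod(dim(cube)[1:2]), ncol = b)
  spectrum(colMeans(flat[idx, , drop = FALSE]), wavelengths)
}

#' Fit a multiplicative scatter correction model
#'
#' MSC removes per-sample multiplicative (slope) and additive (baseline)
#' scatter. The dataset mean spectrum serves as the "ideal spectrum"; each
#' sample is regressed on it by ordinary least squares,
#' `x_i = a_i + b_i * ideal + e_i`, yielding a baseline shift `a_i` and
#' offset (slope) `b_i` per sample.
#'
#' @param spectra numeric matrix, samples in rows, bands in columns.
#' @return an object of class `"msc_model"`: list with `ideal` (mean
#'   spectrum), `a` (intercepts), `b` (slopes).
#' @seealso [msc_apply()] to correct spectra with the fitted coefficients.
#' @export
msc_fit <- function(spectra) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 2L) stop("MSC needs at least 2 spectra")
  ideal <- colMeans(spectra)
  v <- stats::var(ideal) * (length(ideal) - 1) / length(ideal)
  if (v <= .Machine$double.eps * max(1, mean(ideal)^2))
    stop("degenerate reference: ideal spectrum is constant")
  # closed-form simple OLS of each row on the ideal spectrum
  mi <- mean(ideal)
  ci <- ideal - mi
  denom <- sum(ci^2)
  rowm <- rowMeans(spectra)
  b <- as.vector(spectra %*% ci) / denom # sum(ci) = 0, so the mean term drops

  a <- rowm - b * mi
  structure(list(ideal = ideal, a = a, b = b), class = "msc_model")
}

#' @export
print.msc_model <- function(x, ...) {
  cat(sprintf("<msc_model: %d bands, %d samples; slope range [%.3f, %.3f]>\n",
              length(x$ideal), length(x$b), min(x$b), max(x$b)))
  invisible(x)
}

#' Apply multiplicative scatter correction to one spectrum
#'
#' Corrects a spectrum with known scatter coefficients by subtracting the
#' baseline shift and dividing by the offset: `(x - a) / b`.
#'
#' @param x a [spectrum] or numeric reflectance vector.
#' @param a baseline shift (intercept).
#' @param b offset (slope); must exceed `tol` in magnitude.
#' @param tol smallest admissible `|b|` (default `1e-8`).
#' @return corrected spectrum, same type and wavelengths as the input.
#' @export
msc_apply <- function(x, a, b, tol = 1e-8) {
  if (abs(b) <= tol) stop("near-zero offset: |b| <= tolerance, cannot divide")
  if (inherits(x, "spectrum"))
    spectrum((x$reflectance - a) / b, x$wavelengths)
  else (as.numeric(x) - a) / b
}

#' Fit-and-apply MSC over a spectra matrix
#'
#' Convenience wrapper: fits the MSC model on all rows and returns the
#' corrected matrix `(x_i - a_i) / b_i` together with the model.
#'
#' @inheritParams msc_fit
#' @return list with `corrected` (matrix, same shape) and `model`.
#' @export
msc_correct <- function(spectra) {
  spectra <- as.matrix(spectra)
  m <- msc_fit(spectra)
  corrected <- (spectra - m$a) / m$b
  list(corrected = corrected, model = m)
}

#' Min-max normalization of a spectrum
#'
#' Rescales reflectance linearly to the unit interval, preserving the
#' positions of peaks and troughs.
#'
#' @param x a [spectrum] or numeric vector; must not be constant.
#' @return normalized spectrum of the same type, values in `[0, 1]`.
#' @export
normalize_spectrum <- function(x) {
  r <- as_reflectance(x)
  lo <- min(r); hi <- max(r)
  if (hi <= lo) stop("degenerate range: spectrum is constant, cannot normalize")
  out <- (r - lo) / (hi - lo)
  if (inherits(x, "spectrum")) spectrum(out, x$wavelengths) else out
}

#' First derivative of a spectrum
#'
#' Finite-difference derivative of reflectance with respect to wavelength:
#' central differences at interior bands, one-sided differences at the two
#' ends. Output has the same length as the input. Used to locate the
#' wavelength regions where freshness classes separate.
#'
#' @param x a [spectrum], or numeric vector (paired with `wavelengths`).
#' @param wavelengths wavelength grid when `x` is a bare vector.
#' @return derivative spectrum (units: reflectance per nm), same type as input.
#' @export
first_derivative <- function(x, wavelengths = NULL) {
  r <- as_reflectance(x)
  w <- if (inherits(x, "spectrum")) x$wavelengths else
    if (is.null(wavelengths)) default_wavelengths(length(r)) else as.numeric(wavelengths)
  n <- length(r)
  if (n < 3L) stop("too short: first derivative needs at least 3 bands")
  d <- numeric(n)
  d[1] <- (r[2] - r[1]) / (w[2] - w[1])
  d[n] <- (r[n] - r[n - 1]) / (w[n] - w[n - 1])
  i <- 2:(n - 1)
  d[i] <- (r[i + 1] - r[i - 1]) / (w[i + 1] - w[i - 1])
  if (inherits(x, "spectrum")) spectrum(d, w) else d
}
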