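# Distance-correlation band selection. Each spectral band is scored by its
# distance correlation with the (ordinally encoded) freshness label,
# dCor(X, Y) = dCov(X, Y) / sqrt(dVar(X) dVar(Y)), computed from
# double-centred pairwise-distance matrices with the population-style
# (biased, 1/n^2) normalisation. Bands scoring above the threshold
# (strictly greater than 0.7 by default) are kept; the rest are zeroed.

# double-centred absolute-distance matrix
dc_center <- function(x) {
  d <- abs(outer(x, x, "-"))
  rm <- rowMeans(d)
  d - outer(rm, rep(1, length(x))) - outer(rep(1, length(x)), rm) + mean(d)
}

#' Distance correlation of two numeric vectors
#'
#' A dependence measure in `[0, 1]` that is zero (in the population) only
#' under independence, so it also captures non-linear and non-monotone
#' relations between reflectance and freshness. Computed from pairwise
#' distance matrices via double centring; `dCov^2` is the mean of the
#' elementwise product of the centred matrices (biased `1/n^2`
#' normalisation).
#'
#' @param x,y numeric vectors of equal length `n >= 2`.
#' @return scalar in `[0, 1]`; 0 (with a warning) if either input is
#'   constant, by the `dVar = 0` convention.
#' @export
distance_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("shape error: x and y lengths differ")
  if (length(x) < 2L) stop("need at least 2 observations")
  a <- dc_center(x)
  b <- dc_center(y)
  dvx <- mean(a * a)
  dvy <- mean(b * b)
  if (dvx <= 0 || dvy <= 0) {
    warning("constant input: distance variance is zero, returning 0")
    return(0)
  }
  dcov2 <- mean(a * b)
  # numerical floor: dCov^2 is non-negative in exact arithmetic
  sqrt(max(dcov2, 0) / sqrt(dvx * dvy))
}

#' Score all spectral bands against the freshness label
#'
#' Computes the distance correlation of every band with the numerically
#' encoded labels (0--3, ordinal in storage day) and thresholds the scores
#' into a band mask. Runs of selected bands are summarised as wavelength
#' windows.
#'
#' @param spectra numeric `n x B` matrix, typically MSC-corrected.
#' @param labels class codes 0--3, at least two distinct and `n >= 8`.
#' @param threshold selection cut; a band is selected when its score is
#'   strictly greater (default 0.7).
#' @param wavelengths wavelength grid for window reporting.
#' @return object of class `"band_mask"`: list with `scores`, `selected`
#'   (logical), `threshold`, `wavelengths`, `windows` (data frame of
#'   selected runs in nm).
#' @export
score_bands <- function(spectra, labels, threshold = 0.7,
                        wavelengths = default_wavelengths(ncol(spectra))) {
  spectra <- as.matrix(spectra)
  labels <- as.numeric(labels)
  n <- nrow(spectra)
  if (n < 8L) stop("need at least 8 samples (2 per class) to score bands")
  if (length(labels) != n) stop("labels length disagrees with spectra rows")
  if (length(unique(labels)) < 2L)
    stop("degenerate labels: a single class cannot be correlated")
  b_lab <- dc_center(labels)
  dvy <- mean(b_lab * b_lab)
  scores <- vapply(seq_len(ncol(spectra)), function(j) {
    a <- dc_center(spectra[, j])
    dvx <- mean(a * a)
    if (dvx <= 0) return(0)
    sqrt(max(mean(a * b_lab), 0) / sqrt(dvx * dvy))
  }, numeric(1))
  selected <- scores > threshold
  structure(list(scores = scores, selected = selected, threshold = threshold,
                 wavelengths = wavelengths,
                 windows = selected_windows(selected, wavelengths)),
            class = "band_mask")
}

selected_windows <- function(selected, wavelengths) {
  if (!any(selected))
    return(data.frame(from_nm = numeric(0), to_nm = numeric(0),
                      n_bands = integer(0)))
  r <- rle(selected)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(from_nm = wavelengths[starts[keep]],
             to_nm = wavelengths[ends[keep]],
             n_bands = r$lengths[keep])
}

#' @export
print.band_mask <- function(x, ...) {
  cat(sprintf("<band_mask: %d/%d bands > %.2f>\n",
              sum(x$selected), length(x$selected), x$threshold))
  if (nrow(x$windows) > 0) {
    cat("  windows (nm):\n")
    for (i in seq_len(nrow(x$windows)))
      cat(sprintf("    %.1f-%.1f (%d bands)\n", x$windows$from_nm[i],
                  x$windows$to_nm[i], x$windows$n_bands[i]))
  }
  invisible(x)
}

#' Zero-ablate unselected bands
#'
#' Sets every column of the spectra matrix whose band is not selected to
#' exactly zero; selected columns are untouched. Idempotent.
#'
#' @param spectra numeric `n x B` matrix.
#' @param mask a `"band_mask"` or logical vector of length `B`.
#' @return matrix of the same shape.
#' @export
ablate_bands <- function(spectra, mask) {
  spectra <- as.matrix(spectra)
  sel <- if (inherits(mask, "band_mask")) mask$selected else as.logical(mask)
  if (length(sel) != ncol(spectra))
    stop("mask length disagrees with band count")
  spectra[, !sel] <- 0
  spectra
}

#' Serialize a band mask to JSON
#'
#' @param mask a `"band_mask"`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_band_mask <- function(mask, path) {
  jsonlite::write_json(list(threshold = mask$threshold,
                            wavelengths = mask$wavelengths,
                            scores = mask$scores,
                            selected = mask$selected,
                            windows = mask$windows),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
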