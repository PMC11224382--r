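# RGB preprocessing: ROI crop, area-average downsampling to the 22 x 21
# fusion resolution, and CIELAB green-intensity hue.

FUSION_ROWS <- 22L
FUSION_COLS <- 21L

# 1-D area-average resampling weights: rows of the returned n_out x n_in
# matrix hold the fractional coverage of each input cell by the output cell,
# normalised to sum to 1. Exact block means when n_in is a multiple of n_out.
box_weights <- function(n_in, n_out) {
  stopifnot(n_in >= n_out)
  w <- matrix(0, n_out, n_in)
  step <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * step
    hi <- i * step
    j0 <- floor(lo) + 1L
    j1 <- ceiling(hi)
    for (j in j0:min(j1, n_in)) {
      cover <- min(hi, j) - max(lo, j - 1)
      if (cover > 0) w[i, j] <- cover
    }
  }
  w / step
}

#' Crop a region of interest and downsample to the fusion resolution
#'
#' Crops the image to a rectangular pod ROI and resamples it to exactly
#' 22 rows by 21 columns using area-average (box) resampling: each output
#' pixel is the mean of the input area it covers, with fractional coverage
#' at block boundaries. When the crop is an exact integer multiple of
#' 22 x 21 this reduces to plain block means.
#'
#' @param image numeric array `H x W x 3`, values in `[0, 1]` (or 8-bit
#'   integers, which are rescaled).
#' @param roi_box integer vector `c(row0, row1, col0, col1)` in 0-based,
#'   half-open pixel coordinates (`row0 <= r < row1`); `NULL` uses the full
#'   image.
#' @param rows,cols output size (default 22 x 21, the fusion contract).
#' @return numeric array `rows x cols x 3` in `[0, 1]`.
#' @export
crop_downsample <- function(image, roi_box = NULL,
                            rows = FUSION_ROWS, cols = FUSION_COLS) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  if (max(image) > 1) image <- image / 255
  h <- dim(image)[1]; w <- dim(image)[2]
  if (is.null(roi_box)) roi_box <- c(0L, h, 0L, w)
  rb <- as.integer(roi_box)
  if (length(rb) != 4L) stop("roi_box must be c(row0, row1, col0, col1)")
  if (rb[1] < 0 || rb[2] > h || rb[3] < 0 || rb[4] > w)
    stop("bounds error: roi_box outside image")
  if (rb[2] <= rb[1] || rb[4] <= rb[3])
    stop("empty ROI: degenerate roi_box")
  crop <- image[(rb[1] + 1L):rb[2], (rb[3] + 1L):rb[4], , drop = FALSE]
  ch <- dim(crop)[1]; cw <- dim(crop)[2]
  if (ch < rows || cw < cols)
    stop(sprintf("ROI too small: need at least %d x %d pixels", rows, cols))
  wr <- box_weights(ch, rows)
  wc <- box_weights(cw, cols)
  out <- array(0, dim = c(rows, cols, 3L))
  for (k in 1:3) out[, , k] <- wr %*% crop[, , k] %*% t(wc)
  out
}

# sRGB (D65) -> CIE L*a*b*. Gamma expansion, linear transform to XYZ,
# then the standard f(t) nonlinearity against the D65 white point.
srgb_to_lab <- function(rgb) {
  rgb <- matrix(rgb, ncol = 3L)
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  m <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041),
              3, 3, byrow = TRUE)
  xyz <- lin %*% t(m)
  white <- as.numeric(m %*% c(1, 1, 1)) # equal-RGB input maps exactly to a*=b*=0
  tt <- sweep(xyz, 2, white, "/")
  eps <- (6 / 29)^3
  f <- ifelse(tt > eps, tt^(1 / 3), tt / (3 * (6 / 29)^2) + 4 / 29)
  cbind(L = 116 * f[, 2] - 16,
        a = 500 * (f[, 1] - f[, 2]),
        b = 200 * (f[, 2] - f[, 3]))
}

#' Green-intensity colour statistics over a pod ROI
#'
#' Converts masked pixels from sRGB to CIE L*a*b* (D65 white point),
#' averages the three coordinates over the region, and reports the hue
#' parameter `H = arctan(b / a)` -- computed with the two-argument
#' arctangent so the quadrant is preserved, and defined as 0 for
#' achromatic regions (`|a|` and `|b|` below `achromatic_tol`). Green pods
#' have negative `a`; yellowing drives `b` (and the hue) down towards the
#' `+b` axis direction as `a` rises.
#'
#' @param image numeric array `H x W x 3` in `[0, 1]` (8-bit rescaled).
#' @param mask logical `H x W` ROI mask; `NULL` uses all pixels.
#' @param achromatic_tol magnitude below which mean a, b are treated as 0.
#' @return list of class `"color_stats"`: `mean_L`, `mean_a`, `mean_b`,
#'   `hue` (radians).
#' @export
green_intensity <- function(image, mask = NULL, achromatic_tol = 1e-6) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  if (max(image) > 1) image <- image / 255
  h <- dim(image)[1]; w <- dim(image)[2]
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  if (!identical(dim(as.matrix(mask)), c(h, w)))
    stop("mask dimensions disagree with image")
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty ROI: mask selects no pixels")
  flat <- matrix(image, nrow = h * w, ncol = 3L)[idx, , drop = FALSE]
  lab <- srgb_to_lab(flat)
  mL <- mean(lab[, 1]); ma <- mean(lab[, 2]); mb <- mean(lab[, 3])
  hue <- if (abs(ma) < achromatic_tol && abs(mb) < achromatic_tol) 0
         else atan2(mb, ma)
  structure(list(mean_L = mL, mean_a = ma, mean_b = mb, hue = hue),
            class = "color_stats")
}

#' @export
print.color_stats <- function(x, ...) {
  cat(sprintf("<color_stats: L*=%.2f a*=%.2f b*=%.2f hue=%.3f rad>\n",
              x$mean_L, x$mean_a, x$mean_b, x$hue))
  invisible(x)
}
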