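# Fusion of the 462-band spectrum with the 22 x 21 x 3 RGB tensor into the
# 22 x 21 x 4 network input. The channel volume identity
# 22*21*4 = 22*21*3 + 462 is what makes the reshape possible at all.

#' Reshape a spectrum to a two-dimensional plane
#'
#' Fills a `rows x cols` plane with the reflectance values in row-major,
#' wavelength-ascending order: `plane[1, 1]` is band 1, `plane[1, cols]`
#' is band `cols`, `plane[2, 1]` is band `cols + 1`. Flattening the plane
#' row-major recovers the spectrum bitwise.
#'
#' @param x a [spectrum] or numeric vector of length `rows * cols`.
#' @param rows,cols plane size (default 22 x 21, matching 462 bands).
#' @return numeric matrix `rows x cols`.
#' @export
reshape_spectrum_2d <- function(x, rows = FUSION_ROWS, cols = FUSION_COLS) {
  r <- as_reflectance(x)
  if (length(r) != rows * cols)
    stop(sprintf("shape error: %d bands cannot fill a %d x %d plane",
                 length(r), rows, cols))
  matrix(r, nrow = rows, ncol = cols, byrow = TRUE)
}

#' Flatten a spectral plane back to a vector
#'
#' Row-major inverse of [reshape_spectrum_2d()].
#'
#' @param plane numeric matrix.
#' @return numeric vector, `plane` read row by row.
#' @export
flatten_plane <- function(plane) as.vector(t(plane))

#' Fuse an RGB tensor with a spectral plane
#'
#' Concatenates the three RGB channels with the single spectral channel
#' along the channel axis, giving the `22 x 21 x 4` model input. The two
#' modalities have incompatible native scales, so each is scaled
#' per-modality before stacking: RGB to `[0, 1]` (8-bit inputs divided by
#' 255) and the spectral plane min-max per sample to `[0, 1]`. Channel
#' order is (R, G, B, spectral); both sources are recoverable from the
#' fused tensor.
#'
#' @param rgb numeric array `rows x cols x 3`.
#' @param plane numeric matrix `rows x cols` (from [reshape_spectrum_2d()]).
#' @param label optional freshness class code 0--3.
#' @param scale_spectral min-max scale the spectral plane (default TRUE;
#'   disable when the spectrum is already normalized).
#' @return an object of class `"fused_sample"`: list with `tensor`
#'   (`rows x cols x 4`), `label`, and the scaling constants applied.
#' @export
fuse <- function(rgb, plane, label = NA_integer_, scale_spectral = TRUE) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  plane <- as.matrix(plane)
  if (!identical(dim(rgb)[1:2], dim(plane)))
    stop("shape error: RGB and spectral plane spatial dimensions disagree")
  if (!is.na(label) && !(label %in% 0:3)) stop("label must be 0..3 or NA")
  if (max(rgb) > 1) rgb <- rgb / 255
  lo <- min(plane); hi <- max(plane)
  if (scale_spectral) {
    if (hi > lo) plane <- (plane - lo) / (hi - lo) else plane <- plane * 0
  }
  tensor <- array(0, dim = c(dim(plane), 4L))
  tensor[, , 1:3] <- rgb
  tensor[, , 4] <- plane
  structure(list(tensor = tensor, label = as.integer(label),
                 spectral_min = lo, spectral_max = hi),
            class = "fused_sample")
}

#' @export
print.fused_sample <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf("<fused_sample: %d x %d x %d tensor, label %s>\n",
              d[1], d[2], d[3],
              if (is.na(x$label)) "NA" else as.character(x$label)))
  invisible(x)
}

#' Build the fused tensor stack for a whole dataset
#'
#' Runs the standard preprocessing on a paired dataset -- MSC correction of
#' the spectra matrix, downsampling of each RGB image, per-sample reshape
#' and fusion -- and stacks the result into an `n x 22 x 21 x 4` array
#' suitable for [resnet_rh()] and [flatten_features()].
#'
#' @param dataset a `"synthetic_dataset"` (or any list with `spectra`,
#'   `images`, `labels`).
#' @param msc apply multiplicative scatter correction first (default TRUE).
#' @return list with `tensors` (`n x 22 x 21 x 4` array), `labels`,
#'   `spectra` (the corrected spectra matrix actually fused).
#' @export
fuse_dataset <- function(dataset, msc = TRUE) {
  spectra <- dataset$spectra
  if (msc) spectra <- msc_correct(spectra)$corrected
  n <- nrow(spectra)
  stopifnot(n == length(dataset$images), n == length(dataset$labels))
  tensors <- array(0, dim = c(n, FUSION_ROWS, FUSION_COLS, 4L))
  for (i in seq_len(n)) {
    rgb <- crop_downsample(dataset$images[[i]])
    plane <- reshape_spectrum_2d(spectra[i, ])
    tensors[i, , , ] <- fuse(rgb, plane, dataset$labels[i])$tensor
  }
  list(tensors = tensors, labels = dataset$labels, spectra = spectra)
}
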