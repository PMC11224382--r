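# Synthetic paired-data generator.
#
# Emulates the statistical structure of the vegetable-soybean study data:
# 462-band pod reflectance spectra with a peak near 562 nm and a trough near
# 688 nm, class separation confined to planted wavelength windows (strongest
# near 670 nm and 980 nm), per-sample multiplicative/additive scatter, and
# cartoon RGB pod images whose yellowing and brown-spot area grow with
# storage day. Every downstream stage of the pipeline is testable against
# the generator's recorded ground truth.

#' Configuration for the synthetic pod generator
#'
#' @param n_per_class samples per freshness class (classes 0--3 for storage
#'   days 1, 3, 5, 7).
#' @param n_bands number of spectral bands (default 462).
#' @param wavelength_range nm range of the grid (default `c(386, 1004)`).
#' @param spectral_noise_sd i.i.d. reflectance noise added per band.
#' @param scatter_slope_sd log-scale sd of the per-sample multiplicative
#'   scatter slope (slope `b = exp(N(0, sd))`).
#' @param scatter_offset_sd sd of the per-sample additive scatter offset.
#' @param planted_bands list of nm windows (length-2 vectors) carrying class
#'   signal. Defaults mirror the study's separation regions 494--681 nm and
#'   695--764 nm plus the high-correlation near-infrared region around
#'   980 nm.
#' @param rgb_size pixel size `c(H, W)` of generated pod images before
#'   downsampling (default `c(110, 105)`, five times the 22 x 21 fusion
#'   resolution).
#' @param spot_rate_per_class expected brown spots per pod for classes
#'   0--3; non-decreasing models spot spread with storage.
#' @param spot_radius pixel radius range of brown spots.
#' @param spectral_class_map,rgb_class_map integer vectors of length 4
#'   mapping the freshness class to the effective class used by the
#'   spectral and RGB renderers. The identity (default) makes both
#'   modalities informative for all classes; collapsing entries creates
#'   complementary-information designs (e.g. spectra that separate only
#'   early days and images that separate only late days).
#' @param seed RNG seed used by [generate_dataset()].
#' @return an object of class `"generator_config"` (a validated list).
#' @export
generator_config <- function(n_per_class = 104L,
                             n_bands = 462L,
                             wavelength_range = c(386, 1004),
                             spectral_noise_sd = 0.01,
                             scatter_slope_sd = 0.10,
                             scatter_offset_sd = 0.05,
                             planted_bands = list(c(494, 681), c(695, 764), c(960, 1000)),
                             rgb_size = c(110L, 105L),
                             spot_rate_per_class = c(0, 2, 5, 10),
                             spot_radius = c(2, 6),
                             spectral_class_map = 0:3,
                             rgb_class_map = 0:3,
                             seed = 1L) {
  stopifnot(n_per_class >= 1L, n_bands >= 4L,
            length(wavelength_range) == 2L,
            wavelength_range[2] > wavelength_range[1],
            length(rgb_size) == 2L,
            length(spot_rate_per_class) == 4L,
            all(spot_rate_per_class >= 0),
            length(spectral_class_map) == 4L,
            length(rgb_class_map) == 4L,
            all(spectral_class_map %in% 0:3), all(rgb_class_map %in% 0:3))
  for (w in planted_bands) {
    if (length(w) != 2L || w[1] >= w[2] ||
        w[1] < wavelength_range[1] || w[2] > wavelength_range[2])
      stop("planted_bands windows must be increasing nm pairs inside wavelength_range")
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 n_bands = as.integer(n_bands),
                 wavelength_range = as.numeric(wavelength_range),
                 spectral_noise_sd = spectral_noise_sd,
                 scatter_slope_sd = scatter_slope_sd,
                 scatter_offset_sd = scatter_offset_sd,
                 planted_bands = planted_bands,
                 rgb_size = as.integer(rgb_size),
                 spot_rate_per_class = as.numeric(spot_rate_per_class),
                 spot_radius = as.numeric(spot_radius),
                 spectral_class_map = as.integer(spectral_class_map),
                 rgb_class_map = as.integer(rgb_class_map),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(paste0("<generator_config: %d/class, %d bands %g-%g nm, ",
                     "noise %.3g, scatter (%.3g, %.3g), seed %d>\n"),
              x$n_per_class, x$n_bands, x$wavelength_range[1],
              x$wavelength_range[2], x$spectral_noise_sd,
              x$scatter_slope_sd, x$scatter_offset_sd, x$seed))
  invisible(x)
}

# Boolean mask over the wavelength grid of the planted windows.
planted_band_mask <- function(config) {
  w <- default_wavelengths(config$n_bands, config$wavelength_range)
  m <- rep(FALSE, length(w))
  for (win in config$planted_bands) m <- m | (w >= win[1] & w <= win[2])
  m
}

#' Noise-free class template spectrum
#'
#' The base reflectance curve (shared by all classes) has its global maximum
#' at the grid point nearest 562 nm, a trough near 688 nm and a mild
#' near-infrared plateau. Class-dependent deviations are applied only inside
#' the planted windows: a broad depression plus Gaussian components centred
#' at 670 nm and 980 nm, all scaling linearly with the effective class code
#' so that deviation magnitude is monotone in storage day.
#'
#' @param class_code freshness class 0--3.
#' @param config a [generator_config()].
#' @return a [spectrum].
#' @export
class_template <- function(class_code, config = generator_config()) {
  if (length(class_code) != 1L || !(class_code %in% 0:3))
    stop("invalid class: class_code must be one of 0, 1, 2, 3")
  w <- default_wavelengths(config$n_bands, config$wavelength_range)
  base <- 0.35 +
    0.25 * exp(-((w - 562) / 60)^2) -
    0.25 * exp(-((w - 688) / 25)^2) +
    0.15 * stats::plogis((w - 780) / 40)
  eff <- config$spectral_class_map[class_code + 1L]
  mask <- planted_band_mask(config)
  # class deviation: broad floor + sharp informative bumps at 670/980 nm
  shape <- 0.025 + 0.08 * exp(-((w - 670) / 12)^2) + 0.08 * exp(-((w - 980) / 12)^2)
  dev <- -(eff / 3) * shape * mask
  spectrum(base + dev, w)
}

#' Draw one synthetic pod spectrum
#'
#' Takes the class template, applies per-sample affine scatter
#' (`b * template + a` with log-normal `b` and normal `a` -- exactly the
#' family MSC is designed to remove) and adds i.i.d. band noise last.
#' Uses the current RNG stream; seed via `set.seed()` or
#' [generate_dataset()].
#'
#' @inheritParams class_template
#' @return list with `spectrum` (a [spectrum]) and the scatter truth
#'   `a`, `b` actually used.
#' @export
generate_spectrum <- function(class_code, config = generator_config()) {
  tpl <- class_template(class_code, config)
  b <- exp(stats::rnorm(1, 0, config$scatter_slope_sd))
  a <- stats::rnorm(1, 0, config$scatter_offset_sd)
  noise <- if (config$spectral_noise_sd > 0)
    stats::rnorm(config$n_bands, 0, config$spectral_noise_sd) else 0
  list(spectrum = spectrum(b * tpl$reflectance + a + noise, tpl$wavelengths),
       a = a, b = b)
}

#' Draw one synthetic pod image
#'
#' Renders a pod-shaped ellipse on a dark background. The pod hue shifts
#' from green towards yellow monotonically with the effective class code,
#' and brown spots (count Poisson with the class's expected rate, placed
#' uniformly inside the pod) model the rust spotting that spreads with
#' storage. Rendering is deliberately cartoonish; only the monotone class
#' structure matters downstream.
#'
#' @inheritParams class_template
#' @return list with `image` (array `H x W x 3`, values in `[0, 1]`) and
#'   `spot_pixels` (ground-truth brown-spot pixel count).
#' @export
generate_rgb <- function(class_code, config = generator_config()) {
  if (length(class_code) != 1L || !(class_code %in% 0:3))
    stop("invalid class: class_code must be one of 0, 1, 2, 3")
  h <- config$rgb_size[1]; wdt <- config$rgb_size[2]
  if (h < 22L || wdt < 21L)
    stop("size error: rgb_size must be at least 22 x 21")
  eff <- config$rgb_class_map[class_code + 1L]
  # pod body colour: green -> yellow with storage (red rises, green sags)
  pod <- c(0.18 + 0.13 * eff, 0.55 - 0.03 * eff, 0.16)
  bg <- c(0.10, 0.10, 0.12)
  yc <- (h + 1) / 2; xc <- (wdt + 1) / 2
  ry <- 0.42 * h; rx <- 0.38 * wdt
  yy <- matrix(seq_len(h), h, wdt)
  xx <- matrix(seq_len(wdt), h, wdt, byrow = TRUE)
  inside <- ((yy - yc) / ry)^2 + ((xx - xc) / rx)^2 <= 1
  img <- array(0, dim = c(h, wdt, 3))
  for (k in 1:3) img[, , k] <- ifelse(inside, pod[k], bg[k])
  # mild shading so the pod is not flat
  shade <- 1 - 0.15 * (((yy - yc) / ry)^2 + ((xx - xc) / rx)^2)
  for (k in 1:3) img[, , k] <- img[, , k] * ifelse(inside, shade, 1)
  # brown spots, expected count set by the class's spot rate
  rate <- config$spot_rate_per_class[eff + 1L]
  n_spots <- if (rate > 0) stats::rpois(1, rate) else 0L
  spot_px <- 0L
  brown <- c(0.35, 0.20, 0.08)
  if (n_spots > 0) {
    for (s in seq_len(n_spots)) {
      # rejection-free placement: uniform in the inscribed ellipse
      th <- stats::runif(1, 0, 2 * pi); rr <- sqrt(stats::runif(1))
      sy <- yc + 0.85 * ry * rr * sin(th)
      sx <- xc + 0.85 * rx * rr * cos(th)
      srad <- stats::runif(1, config$spot_radius[1], config$spot_radius[2])
      spot <- inside & ((yy - sy)^2 + (xx - sx)^2 <= srad^2)
      spot_px <- spot_px + sum(spot)
      for (k in 1:3) img[, , k] <- ifelse(spot, brown[k], img[, , k])
    }
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img, spot_pixels = spot_px)
}

#' Generate a full paired synthetic dataset
#'
#' Draws `n_per_class` paired (spectrum, RGB image) samples for each of the
#' four freshness classes under the config's seed, and records the ground
#' truth needed to score recovery downstream: planted band indices and the
#' per-sample scatter coefficients.
#'
#' @param config a [generator_config()].
#' @return an object of class `"synthetic_dataset"`: list with
#'   `spectra` (`n x n_bands` matrix), `wavelengths`, `images` (list of
#'   `H x W x 3` arrays), `labels` (integer 0--3), and `truth` (list with
#'   `planted_idx`, `planted_mask`, `scatter_a`, `scatter_b`,
#'   `spot_pixels`, `config`).
#' @export
generate_dataset <- function(config = generator_config()) {
  set.seed(config$seed)
  n <- 4L * config$n_per_class
  labels <- rep(0:3, each = config$n_per_class)
  spectra <- matrix(NA_real_, n, config$n_bands)
  images <- vector("list", n)
  a <- b <- numeric(n)
  spots <- integer(n)
  for (i in seq_len(n)) {
    sp <- generate_spectrum(labels[i], config)
    spectra[i, ] <- sp$spectrum$reflectance
    a[i] <- sp$a; b[i] <- sp$b
    im <- generate_rgb(labels[i], config)
    images[[i]] <- im$image
    spots[i] <- im$spot_pixels
  }
  mask <- planted_band_mask(config)
  structure(list(spectra = spectra,
                 wavelengths = default_wavelengths(config$n_bands,
                                                   config$wavelength_range),
                 images = images,
                 labels = labels,
                 truth = list(planted_idx = which(mask),
                              planted_mask = mask,
                              scatter_a = a, scatter_b = b,
                              spot_pixels = spots,
                              config = config)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset: %d samples (%s), %d bands, images %dx%d>\n",
              length(x$labels),
              paste(table(x$labels), collapse = "/"),
              ncol(x$spectra), dim(x$images[[1]])[1], dim(x$images[[1]])[2]))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Spectra go to a CSV (header row of wavelengths, one sample per row,
#' final column `label`), images to individual PNG files, and a JSON
#' manifest links image files to spectrum rows and labels so the pair can
#' be reloaded with [read_manifest()].
#'
#' @param dataset a `"synthetic_dataset"` from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spectra_csv <- file.path(dir, "spectra.csv")
  df <- as.data.frame(dataset$spectra)
  names(df) <- sprintf("%.2f", dataset$wavelengths)
  df$label <- dataset$labels
  utils::write.csv(df, spectra_csv, row.names = FALSE)
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  img_files <- character(length(dataset$images))
  for (i in seq_along(dataset$images)) {
    img_files[i] <- file.path("images", sprintf("pod_%04d.png", i))
    png::writePNG(dataset$images[[i]], file.path(dir, img_files[i]))
  }
  manifest <- list(spectra_csv = "spectra.csv",
                   n_bands = ncol(dataset$spectra),
                   samples = lapply(seq_along(img_files), function(i)
                     list(row = i, image = img_files[i],
                          label = dataset$labels[i])))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
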