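test_that("class templates peak at 562 nm, trough near 688 nm, and are exact without noise", {
  cfg <- generator_config(n_per_class = 1, spectral_noise_sd = 0,
                          scatter_slope_sd = 0, scatter_offset_sd = 0)
  wl <- default_wavelengths()
  # the base curve troughs at 688 nm; class dips deepen the chlorophyll
  # absorption region, so later-day troughs may sit a few nm blueward
  expect_lt(abs(class_template(0, cfg)$wavelengths[
    which.min(class_template(0, cfg)$reflectance)] - 688), 3)
  for (k in 0:3) {
    tpl <- class_template(k, cfg)
    expect_equal(tpl$wavelengths[which.max(tpl$reflectance)],
                 wl[which.min(abs(wl - 562))])
    trough <- tpl$wavelengths[which.min(tpl$reflectance)]
    expect_true(trough >= 655 && trough <= 700)
    # scatter off, noise off: a draw reproduces the template bitwise
    set.seed(k + 1)
    draw <- generate_spectrum(k, cfg)
    expect_identical(draw$spectrum$reflectance, tpl$reflectance)
    expect_equal(draw$b, 1)
    expect_equal(draw$a, 0)
  }
  expect_error(class_template(4, cfg), "invalid class")
  expect_error(generate_spectrum(-1, cfg), "invalid class")
})

test_that("class signal is confined to the planted windows and monotone in class", {
  cfg <- generator_config()
  mask <- freshfuse:::planted_band_mask(cfg)
  t0 <- class_template(0, cfg)$reflectance
  prev_mag <- 0
  for (k in 1:3) {
    diff_k <- class_template(k, cfg)$reflectance - t0
    expect_true(all(diff_k[!mask] == 0))
    mag <- mean(abs(diff_k[mask]))
    expect_gt(mag, prev_mag)
    prev_mag <- mag
  }
  # truth indices are exactly the bands where templates differ
  t3 <- class_template(3, cfg)$reflectance
  expect_identical(which(t3 != t0), which(mask))
})

test_that("between-class differences concentrate inside the planted windows", {
  cfg <- generator_config(n_per_class = 1)
  mask <- freshfuse:::planted_band_mask(cfg)
  set.seed(7)
  draws0 <- replicate(300, generate_spectrum(0, cfg)$spectrum$reflectance)
  draws3 <- replicate(300, generate_spectrum(3, cfg)$spectrum$reflectance)
  gap <- abs(rowMeans(draws3) - rowMeans(draws0))
  expect_lt(mean(gap[!mask]), mean(gap[mask]))
})

test_that("pod images yellow and gain brown spots with storage day", {
  cfg <- generator_config(rgb_size = c(44, 42),
                          spot_rate_per_class = c(0, 0, 0, 0))
  set.seed(1)
  img0 <- generate_rgb(0, cfg)$image
  img3 <- generate_rgb(3, cfg)$image
  gr <- function(im) mean(im[, , 2]) / mean(im[, , 1])
  expect_gt(gr(img0), gr(img3))
  # determinism: same seed, bit-identical raster
  set.seed(99); a <- generate_rgb(2, cfg)
  set.seed(99); b <- generate_rgb(2, cfg)
  expect_identical(a, b)
  expect_error(generate_rgb(1, generator_config(rgb_size = c(10, 10))),
               "size error")
})

test_that("mean brown-spot area is non-decreasing over classes", {
  cfg <- generator_config(rgb_size = c(44, 42))
  set.seed(11)
  means <- vapply(0:3, function(k)
    mean(replicate(200, generate_rgb(k, cfg)$spot_pixels)), numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("generate_dataset is balanced, sized 4n, and reproducible", {
  ds <- generate_dataset(generator_config(n_per_class = 104,
                                          rgb_size = c(22, 21), seed = 2))
  expect_equal(length(ds$labels), 416)
  expect_equal(unname(table(ds$labels)), rep(104L, 4), ignore_attr = TRUE)
  ds1 <- tiny_dataset(seed = 5)
  expect_equal(length(ds1$labels), 16)
  ds2 <- tiny_dataset(seed = 5)
  expect_identical(ds1, ds2)
  # truth record supports recovery scoring
  expect_true(all(ds1$truth$planted_idx %in% seq_len(462)))
  expect_length(ds1$truth$scatter_a, 16)
})

test_that("dataset round-trips through the CSV/PNG manifest", {
  ds <- tiny_dataset(seed = 8, n_per_class = 2)
  dir <- tempfile("fx")
  mpath <- write_dataset(ds, dir)
  back <- read_manifest(mpath)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$spectra, ds$spectra, ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(back$wavelengths, ds$wavelengths, tolerance = 1e-2)
  # 8-bit PNG quantisation only
  expect_lt(max(abs(back$images[[3]] - ds$images[[3]])), 1 / 255)
  # a missing image is reported with the sample
  file.remove(file.path(dir, "images", "pod_0002.png"))
  expect_error(read_manifest(mpath), "sample 2")
  unlink(dir, recursive = TRUE)
})
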