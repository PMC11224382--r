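test_that("roi_mean_spectrum averages masked pixels per band", {
  # constant cube
  cube <- array(0.4, c(3, 4, 5))
  mask <- matrix(c(TRUE, FALSE), 3, 4)
  expect_equal(roi_mean_spectrum(cube, mask, 1:5)$reflectance, rep(0.4, 5))
  # two-pixel mask: plain average
  cube2 <- array(0, c(2, 2, 3))
  cube2[1, 1, ] <- c(1, 2, 3); cube2[2, 2, ] <- c(3, 4, 5)
  m2 <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  expect_equal(roi_mean_spectrum(cube2, m2, 1:3)$reflectance, c(2, 3, 4))
  # random cube vs explicit loop, and permutation invariance of pixel order
  set.seed(3)
  cube3 <- array(runif(5 * 5 * 20), c(5, 5, 20))
  m3 <- matrix(runif(25) > 0.5, 5, 5)
  got <- roi_mean_spectrum(cube3, m3, 1:20)$reflectance
  want <- numeric(20)
  for (b in 1:20) {
    acc <- 0; cnt <- 0
    for (i in 1:5) for (j in 1:5) if (m3[i, j]) {
      acc <- acc + cube3[i, j, b]; cnt <- cnt + 1
    }
    want[b] <- acc / cnt
  }
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(roi_mean_spectrum(cube3, matrix(FALSE, 5, 5)), "empty ROI")
})

test_that("msc_fit recovers per-sample affine coefficients by OLS", {
  wl <- default_wavelengths(50)
  t <- sin(wl / 100) + 2
  # identical samples: everyone is the ideal, (a, b) = (0, 1)
  same <- matrix(rep(t, 4), 4, byrow = TRUE)
  m <- msc_fit(same)
  expect_equal(m$a, rep(0, 4), tolerance = 1e-12)
  expect_equal(m$b, rep(1, 4), tolerance = 1e-12)
  # general case against the normal-equations oracle
  set.seed(4)
  r <- matrix(rnorm(10 * 462, mean = 3), 10, 462)
  m3 <- msc_fit(r)
  ideal <- colMeans(r)
  for (i in 1:10) {
    o <- ols_oracle(r[i, ], ideal)
    expect_equal(m3$a[i], unname(o["a"]), tolerance = 1e-10)
    expect_equal(m3$b[i], unname(o["b"]), tolerance = 1e-10)
  }
  expect_error(msc_fit(matrix(1, 3, 10)), "constant")
  expect_error(msc_fit(r[1, , drop = FALSE]), "at least 2")
})

test_that("msc_apply inverts the affine distortion", {
  wl <- default_wavelengths(30)
  ideal <- cos(wl / 80) + 2
  s <- spectrum(2 * ideal + 3, wl)
  expect_equal(msc_apply(s, 0, 1)$reflectance, s$reflectance)
  expect_equal(msc_apply(s, 3, 2)$reflectance, ideal, tolerance = 1e-12)
  expect_error(msc_apply(s, 0, 1e-12), "near-zero offset")
})

test_that("fit-then-apply collapses an affine family onto one shape", {
  wl <- default_wavelengths(462)
  t <- 0.3 + 0.2 * exp(-((wl - 562) / 60)^2)
  set.seed(9)
  b <- exp(rnorm(50, 0, 0.2)); a <- rnorm(50, 0, 0.1)
  x <- b %o% t + a
  corr <- msc_correct(x)$corrected
  # every pair of corrected spectra agrees (the scatter is gone)
  rng <- apply(corr, 2, function(col) diff(range(col)))
  expect_lt(max(rng), 1e-8)
  # refitting the corrected spectra gives (a, b) ~ (0, 1)
  m2 <- msc_fit(corr)
  expect_equal(m2$a, rep(0, 50), tolerance = 1e-8)
  expect_equal(m2$b, rep(1, 50), tolerance = 1e-8)
})

test_that("normalize_spectrum min-max scales, preserves order, is idempotent", {
  expect_equal(normalize_spectrum(c(0, 5, 10)), c(0, 0.5, 1))
  v01 <- c(0, 0.2, 0.7, 1)
  expect_equal(normalize_spectrum(v01), v01)
  set.seed(5)
  v <- rnorm(100)
  nv <- normalize_spectrum(v)
  expect_equal(which.max(nv), which.max(v))
  expect_equal(order(nv), order(v))
  expect_equal(normalize_spectrum(nv), nv)
  expect_error(normalize_spectrum(rep(2, 5)), "degenerate range")
})

test_that("first_derivative is exact on ramps and interior quadratics", {
  wl <- default_wavelengths(20)
  expect_equal(first_derivative(spectrum(3 * wl + 1, wl))$reflectance,
               rep(3, 20), tolerance = 1e-10)
  expect_equal(first_derivative(spectrum(rep(2, 20), wl))$reflectance,
               rep(0, 20))
  # central differences are exact for quadratics on a uniform grid
  q <- 0.5 * wl^2 - 3 * wl + 7
  d <- first_derivative(spectrum(q, wl))$reflectance
  expect_equal(d[2:19], (wl - 3)[2:19], tolerance = 1e-6)
  expect_error(first_derivative(c(1, 2)), "at least 3")
})

test_that("derivative analysis of the generator reproduces the separation bands", {
  # the first-derivative gap between extreme classes concentrates where the
  # class signal was planted
  cfg <- generator_config()
  d0 <- first_derivative(class_template(0, cfg))$reflectance
  d3 <- first_derivative(class_template(3, cfg))$reflectance
  wl <- default_wavelengths()
  gap <- abs(d3 - d0)
  inside <- freshfuse:::planted_band_mask(cfg)
  # allow the derivative to bleed one band over the window edge
  edge <- which(inside)
  inside_wide <- inside
  inside_wide[pmax(edge - 1, 1)] <- TRUE
  inside_wide[pmin(edge + 1, length(inside))] <- TRUE
  expect_true(all(gap[!inside_wide] < 1e-12))
  expect_gt(max(gap[inside]), 0)
})
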