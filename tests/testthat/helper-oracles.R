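# Independent oracles used across the suite. Each is written from the
# defining formula, loop by loop, deliberately avoiding the vectorised
# code paths of the package implementation.

# O(n^2) distance correlation straight from the double-centring recipe.
dcor_oracle <- function(x, y) {
  n <- length(x)
  A <- matrix(0, n, n); B <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    A[i, j] <- abs(x[i] - x[j])
    B[i, j] <- abs(y[i] - y[j])
  }
  center <- function(D) {
    out <- matrix(0, n, n)
    gm <- mean(D)
    for (i in 1:n) for (j in 1:n)
      out[i, j] <- D[i, j] - mean(D[i, ]) - mean(D[, j]) + gm
    out
  }
  Ac <- center(A); Bc <- center(B)
  dcov2 <- sum(Ac * Bc) / n^2
  dvx <- sum(Ac * Ac) / n^2
  dvy <- sum(Bc * Bc) / n^2
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(dvx * dvy))
}

# two-parameter OLS by the normal equations, explicitly
ols_oracle <- function(y, x) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x * x); sxy <- sum(x * y)
  det <- n * sxx - sx * sx
  b <- (n * sxy - sx * sy) / det
  a <- (sy - b * sx) / n
  c(a = a, b = b)
}

# Wilson interval by numeric inversion of the score test: the bounds are
# the p solving (p_hat - p)^2 = z^2 p (1 - p) / n on either side of p_hat.
wilson_oracle <- function(n, p_hat, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  g <- function(p) (p_hat - p)^2 - z^2 * p * (1 - p) / n
  lower <- if (g(0) < 0) 0 else uniroot(g, c(0, p_hat), tol = 1e-12)$root
  upper <- if (g(1) < 0) 1 else uniroot(g, c(p_hat, 1), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

# reference colorimetry: scalar, step-by-step sRGB (IEC 61966-2-1) to
# CIE L*a*b* under D65, written independently of the package's
# vectorised conversion
lab_oracle <- function(rgb_matrix) {
  out <- matrix(0, nrow(rgb_matrix), 3, dimnames = list(NULL, c("L", "a", "b")))
  finv <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  for (i in seq_len(nrow(rgb_matrix))) {
    lin <- numeric(3)
    for (k in 1:3) {
      v <- rgb_matrix[i, k]
      lin[k] <- if (v <= 0.04045) v / 12.92 else ((v + 0.055) / 1.055)^2.4
    }
    X <- 0.4124564 * lin[1] + 0.3575761 * lin[2] + 0.1804375 * lin[3]
    Y <- 0.2126729 * lin[1] + 0.7151522 * lin[2] + 0.0721750 * lin[3]
    Z <- 0.0193339 * lin[1] + 0.1191920 * lin[2] + 0.9503041 * lin[3]
    Xn <- 0.4124564 + 0.3575761 + 0.1804375
    Yn <- 0.2126729 + 0.7151522 + 0.0721750
    Zn <- 0.0193339 + 0.1191920 + 0.9503041
    fx <- finv(X / Xn); fy <- finv(Y / Yn); fz <- finv(Z / Zn)
    out[i, ] <- c(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
  }
  out
}

# small paired dataset used by several files
tiny_dataset <- function(seed = 42, n_per_class = 4) {
  generate_dataset(generator_config(n_per_class = n_per_class,
                                    rgb_size = c(44, 42), seed = seed))
}
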