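# Minimal convolutional-network primitives in base R.
#
# Feature maps are stored as arrays of dimension (H, W, N, C) so that a
# (H*W*N) x C matrix view is a zero-copy reshape in column-major R.
# Convolutions are computed as k*k shifted-slice matrix products against
# the (Cin x Cout) kernel slices -- each a single BLAS call -- rather than
# via an explicit im2col buffer.

# ---- convolution ----------------------------------------------------------

conv_init <- function(k, cin, cout) {
  # He initialisation, fan-in = k*k*cin
  array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

conv_out_dim <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

pad_input <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

conv_forward <- function(x, w, stride = 1L, pad = 0L) {
  d <- dim(x)
  k <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  stopifnot(d[4] == cin)
  ho <- conv_out_dim(d[1], k, stride, pad)
  wo <- conv_out_dim(d[2], k, stride, pad)
  xp <- pad_input(x, pad)
  n <- d[3]
  ri <- seq.int(1L, by = stride, length.out = ho)
  ci <- seq.int(1L, by = stride, length.out = wo)
  out <- matrix(0, ho * wo * n, cout)
  for (di in 0:(k - 1L)) for (dj in 0:(k - 1L)) {
    xs <- xp[ri + di, ci + dj, , , drop = FALSE]
    out <- out + matrix(xs, ho * wo * n, cin) %*%
      matrix(w[di + 1L, dj + 1L, , ], cin, cout)
  }
  list(out = array(out, c(ho, wo, n, cout)),
       cache = list(xp = xp, in_dim = d, stride = stride, pad = pad,
                    k = k, ri = ri, ci = ci))
}

conv_backward <- function(dy, w, cache) {
  k <- cache$k; stride <- cache$stride; pad <- cache$pad
  ri <- cache$ri; ci <- cache$ci
  dd <- dim(dy); ho <- dd[1]; wo <- dd[2]; n <- dd[3]; cout <- dd[4]
  cin <- dim(w)[3]
  dym <- matrix(dy, ho * wo * n, cout)
  dxp <- array(0, dim(cache$xp))
  dw <- array(0, dim(w))
  for (di in 0:(k - 1L)) for (dj in 0:(k - 1L)) {
    xs <- cache$xp[ri + di, ci + dj, , , drop = FALSE]
    xm <- matrix(xs, ho * wo * n, cin)
    dw[di + 1L, dj + 1L, , ] <- crossprod(xm, dym)
    dxs <- array(tcrossprod(dym, matrix(w[di + 1L, dj + 1L, , ], cin, cout)),
                 c(ho, wo, n, cin))
    dxp[ri + di, ci + dj, , ] <- dxp[ri + di, ci + dj, , , drop = FALSE] + dxs
  }
  d <- cache$in_dim
  dx <- if (pad > 0L)
    dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE]
  else dxp
  list(dx = dx, dw = dw)
}

# ---- batch normalization --------------------------------------------------

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c))
}

bn_buffers_init <- function(c) {
  list(mean = rep(0, c), var = rep(1, c))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

bn_forward <- function(x, par, buf, train = TRUE) {
  d <- dim(x)
  m <- prod(d[1:3])
  xm <- matrix(x, m, d[4])
  if (train) {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu * mu # population variance
    buf$mean <- BN_MOMENTUM * buf$mean + (1 - BN_MOMENTUM) * mu
    buf$var <- BN_MOMENTUM * buf$var + (1 - BN_MOMENTUM) * va
  } else {
    mu <- buf$mean
    va <- buf$var
  }
  invstd <- 1 / sqrt(va + BN_EPS)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, invstd, "*")
  y <- sweep(sweep(xhat, 2, par$gamma, "*"), 2, par$beta, "+")
  list(out = array(y, d), buf = buf,
       cache = list(xhat = xhat, invstd = invstd, d = d))
}

bn_backward <- function(dy, par, cache) {
  d <- cache$d
  m <- prod(d[1:3])
  dym <- matrix(dy, m, d[4])
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, par$gamma, "*")
  t1 <- sweep(dxhat, 2, colSums(dxhat) / m, "-")
  t2 <- sweep(xhat, 2, colSums(dxhat * xhat) / m, "*")
  dx <- sweep(t1 - t2, 2, cache$invstd, "*")
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- activations, pooling, linear, loss -----------------------------------

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_backward <- function(dy, mask) dy * mask

global_avgpool_forward <- function(x) {
  d <- dim(x)
  # (H,W,N,C) -> (N,C) mean over the spatial plane
  xm <- matrix(aperm(x, c(3, 4, 1, 2)), d[3] * d[4], d[1] * d[2])
  list(out = matrix(rowMeans(xm), d[3], d[4]), cache = d)
}

global_avgpool_backward <- function(dy, d) {
  # spread the gradient evenly over the H*W positions
  g <- dy / (d[1] * d[2])
  aperm(array(g, c(d[3], d[4], d[1], d[2])), c(3, 4, 1, 2))
}

linear_init <- function(cin, cout) {
  list(w = matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
       b = rep(0, cout))
}

linear_forward <- function(x, par) {
  list(out = sweep(x %*% par$w, 2, par$b, "+"), cache = x)
}

linear_backward <- function(dy, par, cache) {
  list(dx = tcrossprod(dy, par$w),
       dw = crossprod(cache, dy),
       db = colSums(dy))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy over integer labels 1..K; returns loss and dlogits
cross_entropy <- function(logits, labels1) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(n), labels1)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / n, probs = p)
}

# ---- parameter-tree utilities and Adam ------------------------------------

# apply f over the numeric leaves of parallel, identically shaped trees
tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    out <- vector("list", length(trees[[1]]))
    names(out) <- names(trees[[1]])
    for (i in seq_along(trees[[1]]))
      out[[i]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    out
  } else {
    do.call(f, trees)
  }
}

adam_init <- function(weights) {
  list(m = tree_map(function(w) w * 0, weights),
       v = tree_map(function(w) w * 0, weights),
       t = 0L)
}

adam_step <- function(weights, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                      state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  weights <- tree_map(function(w, m, v)
    w - lr * (m / bc1) / (sqrt(v / bc2) + eps),
    weights, state$m, state$v)
  list(weights = weights, state = state)
}
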