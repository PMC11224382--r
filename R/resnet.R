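# The ResNet-R&H classifier: conv1 (3x3, stride 1, pad 1, batch norm) into
# four stages -- stage 1 holds two plain residual modules, stages 2-4 each
# hold one downsampling convolutional module (stride-2 branch, kernel-1
# shortcut convolution) and one plain residual module -- followed by a
# global average pool and a linear head with one score per freshness class.
# Eight residual/convolutional modules in total.
#
# A residual module computes activation(h(x) + F(x, w)) where F is
# conv-bn-relu-conv-bn and h is the identity (plain) or a stride-2
# kernel-1 convolution with batch norm (downsampling).

#' Create one residual/convolutional module
#'
#' @param in_channels,out_channels channel counts; a plain module requires
#'   them equal (identity shortcut).
#' @param type `"plain"` (identity shortcut, stride 1) or `"down"`
#'   (stride-2 branch with a kernel-1 shortcut convolution).
#' @return list with `weights`, `buffers`, `type`, `in_channels`,
#'   `out_channels`.
#' @export
residual_module <- function(in_channels, out_channels,
                            type = c("plain", "down")) {
  type <- match.arg(type)
  if (type == "plain" && in_channels != out_channels)
    stop("architecture error: plain module needs in_channels == out_channels")
  w <- list(w1 = conv_init(3L, in_channels, out_channels),
            bn1 = bn_init(out_channels),
            w2 = conv_init(3L, out_channels, out_channels),
            bn2 = bn_init(out_channels))
  b <- list(bn1 = bn_buffers_init(out_channels),
            bn2 = bn_buffers_init(out_channels))
  if (type == "down") {
    w$ws <- conv_init(1L, in_channels, out_channels)
    w$bns <- bn_init(out_channels)
    b$bns <- bn_buffers_init(out_channels)
  }
  list(weights = w, buffers = b, type = type,
       in_channels = in_channels, out_channels = out_channels)
}

# forward through one module; x is (H, W, N, C)
module_forward <- function(wm, bm, x, type, train = TRUE, activation = TRUE) {
  s1 <- if (type == "down") 2L else 1L
  c1 <- conv_forward(x, wm$w1, stride = s1, pad = 1L)
  b1 <- bn_forward(c1$out, wm$bn1, bm$bn1, train)
  r1 <- relu_forward(b1$out)
  c2 <- conv_forward(r1$out, wm$w2, stride = 1L, pad = 1L)
  b2 <- bn_forward(c2$out, wm$bn2, bm$bn2, train)
  bm$bn1 <- b1$buf; bm$bn2 <- b2$buf
  cache <- list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                c2 = c2$cache, b2 = b2$cache)
  if (type == "down") {
    sc <- conv_forward(x, wm$ws, stride = 2L, pad = 0L)
    sb <- bn_forward(sc$out, wm$bns, bm$bns, train)
    bm$bns <- sb$buf
    h <- sb$out
    cache$sc <- sc$cache; cache$sb <- sb$cache
  } else {
    if (!identical(dim(x), dim(b2$out)))
      stop("architecture error: branch and shortcut shapes disagree")
    h <- x
  }
  y <- h + b2$out
  if (activation) {
    ra <- relu_forward(y)
    cache$ra <- ra$cache
    out <- ra$out
  } else {
    out <- y
  }
  list(out = out, branch = b2$out, buffers = bm, cache = cache)
}

module_backward <- function(wm, dy, cache, type, activation = TRUE) {
  if (activation) dy <- relu_backward(dy, cache$ra)
  # branch path
  b2b <- bn_backward(dy, wm$bn2, cache$b2)
  c2b <- conv_backward(b2b$dx, wm$w2, cache$c2)
  r1b <- relu_backward(c2b$dx, cache$r1)
  b1b <- bn_backward(r1b, wm$bn1, cache$b1)
  c1b <- conv_backward(b1b$dx, wm$w1, cache$c1)
  g <- list(w1 = c1b$dw,
            bn1 = list(gamma = b1b$dgamma, beta = b1b$dbeta),
            w2 = c2b$dw,
            bn2 = list(gamma = b2b$dgamma, beta = b2b$dbeta))
  # shortcut path
  if (type == "down") {
    sbb <- bn_backward(dy, wm$bns, cache$sb)
    scb <- conv_backward(sbb$dx, wm$ws, cache$sc)
    g$ws <- scb$dw
    g$bns <- list(gamma = sbb$dgamma, beta = sbb$dbeta)
    dx <- c1b$dx + scb$dx
  } else {
    dx <- c1b$dx + dy
  }
  list(dx = dx, grads = g)
}

#' Forward pass through a single residual module
#'
#' Computes `activation(h(x) + F(x, w))` for one module, exposing the
#' branch output `F(x, w)` so the telescoping identity of deep residual
#' composition (`x_L = x_l` plus the sum of the branch outputs, before
#' final activations) can be checked directly.
#'
#' @param module a [residual_module()].
#' @param x input: array `H x W x C` (one sample) or `H x W x N x C`.
#' @param train use batch statistics (TRUE) or running statistics (FALSE)
#'   in the batch-norm layers.
#' @param activation apply the final ReLU (default TRUE); FALSE returns
#'   the pre-activation sum `h(x) + F(x, w)`.
#' @return list with `out` (same layout as `x`), `branch` (`F(x, w)`), and
#'   the module with updated batch-norm buffers.
#' @export
residual_forward <- function(module, x, train = FALSE, activation = TRUE) {
  single <- length(dim(x)) == 3L
  if (single) x <- array(x, dim = c(dim(x)[1:2], 1L, dim(x)[3]))
  if (dim(x)[4] != module$in_channels)
    stop("architecture error: input channels disagree with the module")
  fw <- module_forward(module$weights, module$buffers, x, module$type,
                       train = train, activation = activation)
  module$buffers <- fw$buffers
  out <- fw$out; branch <- fw$branch
  if (single) {
    out <- array(out, dim(out)[c(1, 2, 4)])
    branch <- array(branch, dim(branch)[c(1, 2, 4)])
  }
  list(out = out, branch = branch, module = module)
}

#' Zero the residual branches of a module or fitted network
#'
#' Sets every branch convolution weight (and branch batch-norm scale/shift)
#' to zero so each module's `F(x, w)` term vanishes: a plain module then
#' acts as `activation(x)` -- the identity on non-negative input -- and the
#' trunk reduces to a fixed transform of the conv1 output.
#'
#' @param x a [residual_module()] or a fitted/built [resnet_rh] object.
#' @return the object with zeroed branches.
#' @export
zero_branches <- function(x) {
  zero_mod <- function(w) {
    w$w1[] <- 0; w$w2[] <- 0
    w$bn1$gamma[] <- 0; w$bn1$beta[] <- 0
    w$bn2$gamma[] <- 0; w$bn2$beta[] <- 0
    w
  }
  if (inherits(x, "resnet_rh")) {
    for (s in seq_along(x$weights$stages))
      for (m in seq_along(x$weights$stages[[s]]))
        x$weights$stages[[s]][[m]] <- zero_mod(x$weights$stages[[s]][[m]])
  } else {
    x$weights <- zero_mod(x$weights)
  }
  x
}

# ---- whole-network assembly ----------------------------------------------

#' Build an untrained freshness network
#'
#' Assembles the architecture: conv1 (3x3, stride 1, padding 1, batch
#' norm, `width` output channels), stage 1 with two plain residual modules
#' at `width`, stages 2-4 each with one downsampling module (channel count
#' doubling, stride 2, kernel-1 shortcut) and one plain module, global
#' average pooling, and a linear layer to `n_classes` scores.
#'
#' @param in_channels input channels: 4 for fused tensors, 3 for RGB-only,
#'   1 for spectral-only ablations.
#' @param n_classes number of freshness classes (default 4).
#' @param width conv1 output channels (default 64); stages use
#'   `width, 2*width, 4*width, 8*width`.
#' @param seed RNG seed for weight initialisation.
#' @return an untrained object of class `"resnet_rh"`.
#' @export
build_resnet <- function(in_channels = 4L, n_classes = 4L, width = 64L,
                         seed = NULL) {
  stopifnot(in_channels >= 1L, n_classes >= 2L, width >= 1L)
  if (!is.null(seed)) set.seed(seed)
  widths <- width * c(1L, 2L, 4L, 8L)
  types <- list(c("plain", "plain"), c("down", "plain"),
                c("down", "plain"), c("down", "plain"))
  stages_w <- stages_b <- vector("list", 4L)
  tab <- NULL
  prev <- width
  for (s in 1:4) {
    mods_w <- mods_b <- vector("list", length(types[[s]]))
    for (m in seq_along(types[[s]])) {
      mod <- residual_module(prev, widths[s], types[[s]][m])
      mods_w[[m]] <- mod$weights
      mods_b[[m]] <- mod$buffers
      tab <- rbind(tab, data.frame(stage = s, module = m,
                                   type = types[[s]][m],
                                   in_channels = prev,
                                   out_channels = widths[s],
                                   stride = if (types[[s]][m] == "down") 2L else 1L))
      prev <- widths[s]
    }
    stages_w[[s]] <- mods_w
    stages_b[[s]] <- mods_b
  }
  weights <- list(conv1 = list(w = conv_init(3L, in_channels, width),
                               bn = bn_init(width)),
                  stages = stages_w,
                  fc = linear_init(widths[4], n_classes))
  buffers <- list(conv1 = bn_buffers_init(width), stages = stages_b)
  structure(list(weights = weights, buffers = buffers,
                 spec = list(in_channels = as.integer(in_channels),
                             n_classes = as.integer(n_classes),
                             width = as.integer(width),
                             module_table = tab),
                 history = NULL, trained = FALSE),
            class = "resnet_rh")
}

# forward pass; x in internal (H, W, N, C) layout
resnet_forward <- function(object, x, train = TRUE, want_cache = FALSE) {
  W <- object$weights; B <- object$buffers
  if (dim(x)[4] != object$spec$in_channels)
    stop(sprintf("shape error: model expects %d input channels, got %d",
                 object$spec$in_channels, dim(x)[4]))
  caches <- list()
  c1 <- conv_forward(x, W$conv1$w, stride = 1L, pad = 1L)
  b1 <- bn_forward(c1$out, W$conv1$bn, B$conv1, train)
  B$conv1 <- b1$buf
  r1 <- relu_forward(b1$out)
  caches$conv1 <- list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache)
  h <- r1$out
  tab <- object$spec$module_table
  caches$stages <- vector("list", 4L)
  for (s in 1:4) {
    caches$stages[[s]] <- vector("list", length(W$stages[[s]]))
    for (m in seq_along(W$stages[[s]])) {
      type <- tab$type[tab$stage == s & tab$module == m]
      fw <- module_forward(W$stages[[s]][[m]], B$stages[[s]][[m]], h, type,
                           train = train)
      B$stages[[s]][[m]] <- fw$buffers
      caches$stages[[s]][[m]] <- fw$cache
      h <- fw$out
    }
  }
  pool <- global_avgpool_forward(h)
  fc <- linear_forward(pool$out, W$fc)
  caches$pool <- pool$cache
  caches$fc <- fc$cache
  list(logits = fc$out, buffers = B,
       caches = if (want_cache) caches else NULL)
}

resnet_backward <- function(object, caches, dlogits) {
  W <- object$weights
  tab <- object$spec$module_table
  fcb <- linear_backward(dlogits, W$fc, caches$fc)
  dh <- global_avgpool_backward(fcb$dx, caches$pool)
  gstages <- vector("list", 4L)
  for (s in 4:1) {
    nm <- length(W$stages[[s]])
    gstages[[s]] <- vector("list", nm)
    for (m in nm:1) {
      type <- tab$type[tab$stage == s & tab$module == m]
      mb <- module_backward(W$stages[[s]][[m]], dh,
                            caches$stages[[s]][[m]], type)
      gstages[[s]][[m]] <- mb$grads
      dh <- mb$dx
    }
  }
  dh <- relu_backward(dh, caches$conv1$r1)
  b1b <- bn_backward(dh, W$conv1$bn, caches$conv1$b1)
  c1b <- conv_backward(b1b$dx, W$conv1$w, caches$conv1$c1)
  list(conv1 = list(w = c1b$dw,
                    bn = list(gamma = b1b$dgamma, beta = b1b$dbeta)),
       stages = gstages,
       fc = list(w = fcb$dw, b = fcb$db))
}

#' Audit the architecture of a freshness network
#'
#' Reports the input-channel count, number of output classes, and the
#' residual/convolutional modules across the four stages (eight in the
#' standard build).
#'
#' @param object a `"resnet_rh"` object.
#' @return list with `in_channels`, `n_classes`, `n_modules`, and a
#'   `modules` data frame (stage, module, type, channels, stride).
#' @export
model_audit <- function(object) {
  stopifnot(inherits(object, "resnet_rh"))
  tab <- object$spec$module_table
  list(in_channels = object$spec$in_channels,
       n_classes = object$spec$n_classes,
       n_modules = nrow(tab),
       modules = tab)
}
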