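# Fitting and prediction for the freshness network.

# Accept an N x H x W x C array, a list of H x W x C arrays, or the list
# returned by fuse_dataset(); return the N x H x W x C stack.
as_tensor_stack <- function(x) {
  if (is.list(x) && !is.null(x$tensors)) return(x$tensors)
  if (is.array(x) && length(dim(x)) == 4L) return(x)
  if (is.array(x) && length(dim(x)) == 3L)
    return(array(x, dim = c(1L, dim(x))))
  if (is.list(x)) {
    arrs <- lapply(x, function(s) if (inherits(s, "fused_sample")) s$tensor else s)
    d <- dim(arrs[[1]])
    out <- array(0, dim = c(length(arrs), d))
    for (i in seq_along(arrs)) out[i, , , ] <- arrs[[i]]
    return(out)
  }
  stop("cannot interpret x as a stack of image tensors")
}

#' Fit the residual freshness classifier
#'
#' Trains the fused-input residual network on `22 x 21 x C` tensors
#' (C = 4 fused, 3 RGB-only, 1 spectral-only) with a cross-entropy
#' objective and the Adam optimizer. By default the data are split
#' stratified 70/30 under the given seed and the held-out 30% is scored
#' each epoch; final-epoch weights are returned unless `keep_best` asks
#' for the epoch with the lowest training loss.
#'
#' @param x samples: `N x 22 x 21 x C` array, list of `22 x 21 x C`
#'   arrays/[fuse()] results, or the output of [fuse_dataset()].
#' @param y freshness class codes 0--3 (integer or factor).
#' @param width conv1 channel count (default 64; stage widths double).
#' @param epochs training epochs (default 100).
#' @param batch_size minibatch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param train_fraction training fraction for the internal stratified
#'   split (default 0.70).
#' @param split optional precomputed list with `train`/`test` index
#'   vectors (overrides `train_fraction`); pass `list(train = seq_along(y),
#'   test = integer(0))` to train on everything.
#' @param n_classes number of classes (default 4).
#' @param seed RNG seed covering the split, weight initialisation and
#'   minibatch shuffling.
#' @param keep_best retain the weights from the epoch with the lowest
#'   training loss instead of the final epoch (default FALSE).
#' @param verbose print a line per epoch.
#' @return an object of class `"resnet_rh"` with elements `weights`,
#'   `buffers`, `spec`, `history` (per-epoch data frame with columns
#'   `epoch`, `train_loss`, `train_acc`, `test_acc`), `split`, `config`.
#' @seealso [predict.resnet_rh()], [model_audit()], [build_resnet()]
#' @examples
#' cfg <- generator_config(n_per_class = 6, rgb_size = c(44, 42), seed = 7)
#' ds <- generate_dataset(cfg)
#' fused <- fuse_dataset(ds)
#' fit <- resnet_rh(fused, ds$labels, width = 4, epochs = 2, seed = 7)
#' predict(fit, fused$tensors[1, , , , drop = FALSE])
#' @export
resnet_rh <- function(x, y, width = 64L, epochs = 100L, batch_size = 32L,
                      lr = 1e-3, train_fraction = 0.7, split = NULL,
                      n_classes = 4L, seed = 1L, keep_best = FALSE,
                      verbose = FALSE) {
  xs <- as_tensor_stack(x)
  y <- as.integer(if (is.factor(y)) as.integer(as.character(y)) else y)
  n <- dim(xs)[1]
  stopifnot(length(y) == n, epochs >= 1L, batch_size >= 1L)
  if (any(y < 0 | y >= n_classes)) stop("labels must lie in 0..n_classes-1")
  set.seed(seed)
  if (is.null(split)) split <- stratified_split(y, train_fraction)
  tr <- split$train; te <- split$test
  if (length(unique(y[tr])) < 2L)
    stop("stratification error: fewer than 2 classes in the training split")
  model <- build_resnet(dim(xs)[4], n_classes, width)
  xint <- aperm(xs, c(2, 3, 1, 4)) # internal (H, W, N, C) layout
  state <- adam_init(model$weights)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), test_acc = numeric(0))
  best <- list(loss = Inf, weights = NULL, buffers = NULL, epoch = NA_integer_)
  for (e in seq_len(epochs)) {
    ord <- sample(tr)
    nb <- ceiling(length(ord) / batch_size)
    tot_loss <- 0; tot_correct <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, length(ord))]
      xb <- xint[, , idx, , drop = FALSE]
      fw <- resnet_forward(model, xb, train = TRUE, want_cache = TRUE)
      model$buffers <- fw$buffers
      ce <- cross_entropy(fw$logits, y[idx] + 1L)
      tot_loss <- tot_loss + ce$loss * length(idx)
      tot_correct <- tot_correct +
        sum(max.col(ce$probs, ties.method = "first") == y[idx] + 1L)
      if (lr > 0) {
        grads <- resnet_backward(model, fw$caches, ce$dlogits)
        up <- adam_step(model$weights, grads, state, lr)
        model$weights <- up$weights
        state <- up$state
      }
    }
    train_loss <- tot_loss / length(tr)
    train_acc <- tot_correct / length(tr)
    test_acc <- if (length(te) > 0) {
      pred <- predict_internal(model, xint[, , te, , drop = FALSE])
      mean(pred == y[te])
    } else NA_real_
    hist <- rbind(hist, data.frame(epoch = e, train_loss = train_loss,
                                   train_acc = train_acc, test_acc = test_acc))
    if (keep_best && train_loss < best$loss)
      best <- list(loss = train_loss, weights = model$weights,
                   buffers = model$buffers, epoch = e)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  train acc %.3f  test acc %s",
                      e, train_loss, train_acc,
                      if (is.na(test_acc)) "-" else sprintf("%.3f", test_acc)))
  }
  if (keep_best && !is.null(best$weights)) {
    model$weights <- best$weights
    model$buffers <- best$buffers
  }
  model$history <- hist
  model$split <- split
  model$trained <- TRUE
  model$config <- list(width = width, epochs = epochs,
                       batch_size = batch_size, lr = lr,
                       train_fraction = train_fraction, seed = seed,
                       keep_best = keep_best,
                       best_epoch = if (keep_best) best$epoch else epochs)
  model
}

# evaluation-mode class codes (0-based) for an internal-layout stack
predict_internal <- function(model, xint, chunk = 64L) {
  n <- dim(xint)[3]
  out <- integer(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- resnet_forward(model, xint[, , idx, , drop = FALSE], train = FALSE)
    out[idx] <- max.col(fw$logits, ties.method = "first") - 1L
  }
  out
}

#' Predict freshness classes with a fitted network
#'
#' Runs the network in evaluation mode (batch-norm running statistics).
#' Class scores are softmax probabilities; the predicted class is the
#' argmax, with ties resolved to the lowest class code.
#'
#' @param object a fitted [resnet_rh] model.
#' @param newdata samples in any form accepted by [resnet_rh()].
#' @param type `"class"` for codes 0--3 (default) or `"prob"` for the
#'   `n x n_classes` score matrix.
#' @param ... unused.
#' @return integer class codes or a probability matrix.
#' @export
predict.resnet_rh <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  xs <- as_tensor_stack(newdata)
  if (dim(xs)[4] != object$spec$in_channels)
    stop(sprintf("shape error: model expects %d channels, got %d",
                 object$spec$in_channels, dim(xs)[4]))
  xint <- aperm(xs, c(2, 3, 1, 4))
  if (type == "class") return(predict_internal(object, xint))
  n <- dim(xint)[3]
  probs <- NULL
  for (start in seq(1L, n, by = 64L)) {
    idx <- start:min(start + 63L, n)
    fw <- resnet_forward(object, xint[, , idx, , drop = FALSE], train = FALSE)
    probs <- rbind(probs, softmax_rows(fw$logits))
  }
  probs
}

#' @export
print.resnet_rh <- function(x, ...) {
  a <- model_audit(x)
  cat(sprintf("ResNet-R&H freshness classifier (%s)\n",
              if (isTRUE(x$trained)) "trained" else "untrained"))
  cat(sprintf("  input channels: %d, classes: %d, conv1 width: %d\n",
              a$in_channels, a$n_classes, x$spec$width))
  cat(sprintf("  residual/convolutional modules: %d\n", a$n_modules))
  if (!is.null(x$history) && nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  after %d epochs: train acc %.3f, test acc %s\n",
                last$epoch, last$train_acc,
                if (is.na(last$test_acc)) "-" else sprintf("%.3f", last$test_acc)))
  }
  invisible(x)
}

#' @export
summary.resnet_rh <- function(object, ...) {
  print(object)
  cat("\nModule audit:\n")
  print(model_audit(object)$modules, row.names = FALSE)
  if (!is.null(object$config)) {
    cat(sprintf("\nTraining: Adam lr %g, batch %d, %d epochs, seed %d\n",
                object$config$lr, object$config$batch_size,
                object$config$epochs, object$config$seed))
  }
  invisible(object)
}

#' Plot training history
#'
#' @param x a fitted [resnet_rh] model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.resnet_rh <- function(x, ...) {
  if (is.null(x$history) || nrow(x$history) == 0)
    stop("no training history to plot")
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "Loss", ...)
  graphics::matplot(h$epoch, cbind(h$train_acc, h$test_acc), type = "l",
                    lty = 1:2, col = c("black", "red"), xlab = "epoch",
                    ylab = "accuracy", main = "Accuracy", ...)
  graphics::legend("bottomright", c("train", "test"), lty = 1:2,
                   col = c("black", "red"), bty = "n")
  invisible(x)
}
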