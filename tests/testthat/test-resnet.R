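test_that("a zeroed-branch residual module is the identity on non-negative input", {
  set.seed(1)
  mod <- zero_branches(residual_module(3, 3, "plain"))
  x <- array(abs(rnorm(6 * 5 * 3)), c(6, 5, 3))
  out <- residual_forward(mod, x, train = TRUE)
  expect_equal(out$out, x, tolerance = 1e-12)
  expect_equal(max(abs(out$branch)), 0)
  # with signed input the module acts as plain ReLU
  xs <- array(rnorm(6 * 5 * 3), c(6, 5, 3))
  outs <- residual_forward(mod, xs, train = TRUE)
  expect_equal(outs$out, pmax(xs, 0), tolerance = 1e-12)
})

test_that("deep composition telescopes: x_L = x_l + sum of branch outputs", {
  set.seed(2)
  mods <- lapply(1:3, function(i) residual_module(4, 4, "plain"))
  x <- array(rnorm(5 * 5 * 4, mean = 1), c(5, 5, 4))
  h <- x
  branch_sum <- array(0, dim(x))
  for (m in mods) {
    fw <- residual_forward(m, h, train = TRUE, activation = FALSE)
    branch_sum <- branch_sum + fw$branch
    h <- fw$out
  }
  expect_equal(h, x + branch_sum, tolerance = 1e-10)
})

test_that("one residual module equals a hand-assembled layer stack", {
  set.seed(3)
  mod <- residual_module(2, 2, "plain")
  x <- array(rnorm(4 * 4 * 1 * 2), c(4, 4, 1, 2))
  got <- residual_forward(mod, x, train = TRUE)$out
  # manual conv -> bn -> relu -> conv -> bn + shortcut -> relu
  w <- mod$weights
  manual_bn <- function(z, par) {
    m <- apply(z, 4, mean)
    v <- apply(z, 4, function(c) mean(c^2) - mean(c)^2)
    for (c in 1:dim(z)[4])
      z[, , , c] <- (z[, , , c] - m[c]) / sqrt(v[c] + 1e-5) * par$gamma[c] +
        par$beta[c]
    z
  }
  c1 <- freshfuse:::conv_forward(x, w$w1, 1, 1)$out
  r1 <- pmax(manual_bn(c1, w$bn1), 0)
  c2 <- freshfuse:::conv_forward(r1, w$w2, 1, 1)$out
  want <- pmax(manual_bn(c2, w$bn2) + x, 0)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("a downsampling module halves the grid through a kernel-1 shortcut", {
  set.seed(4)
  mod <- residual_module(4, 8, "down")
  x <- array(rnorm(22 * 21 * 2 * 4), c(22, 21, 2, 4))
  out <- residual_forward(mod, x, train = TRUE)$out
  expect_equal(dim(out), c(11L, 11L, 2L, 8L))
  expect_equal(dim(mod$weights$ws), c(1L, 1L, 4L, 8L))
  expect_error(residual_module(4, 8, "plain"), "architecture error")
})

test_that("the built model audits 8 modules and scores batches as n x 4", {
  set.seed(5)
  model <- build_resnet(in_channels = 4, n_classes = 4, width = 4)
  a <- model_audit(model)
  expect_equal(a$in_channels, 4L)
  expect_equal(a$n_classes, 4L)
  expect_equal(a$n_modules, 8L)
  expect_equal(sum(a$modules$type == "down"), 3L)
  x <- array(runif(5 * 22 * 21 * 4), c(5, 22, 21, 4))
  xint <- aperm(x, c(2, 3, 1, 4))
  logits <- freshfuse:::resnet_forward(model, xint, train = TRUE)$logits
  expect_equal(dim(logits), c(5L, 4L))
  # RGB-only and spectral-only variants build and run
  for (ch in c(3L, 1L)) {
    m <- build_resnet(in_channels = ch, width = 4)
    xi <- aperm(x[, , , seq_len(ch), drop = FALSE], c(2, 3, 1, 4))
    expect_equal(dim(freshfuse:::resnet_forward(m, xi, train = TRUE)$logits),
                 c(5L, 4L))
  }
  expect_error(freshfuse:::resnet_forward(model,
                                          aperm(x[, , , 1:3, drop = FALSE],
                                                c(2, 3, 1, 4)), TRUE),
               "shape error")
})

test_that("network gradients agree with finite differences", {
  set.seed(6)
  model <- build_resnet(in_channels = 2, n_classes = 3, width = 2)
  x <- array(rnorm(8 * 9 * 4 * 2), c(8, 9, 4, 2))
  y1 <- c(1L, 2L, 3L, 1L)
  loss_at <- function(m) {
    fw <- freshfuse:::resnet_forward(m, x, train = TRUE)
    freshfuse:::cross_entropy(fw$logits, y1)$loss
  }
  fw <- freshfuse:::resnet_forward(model, x, train = TRUE, want_cache = TRUE)
  ce <- freshfuse:::cross_entropy(fw$logits, y1)
  g <- freshfuse:::resnet_backward(model, fw$caches, ce$dlogits)
  eps <- 1e-5
  # probe a handful of parameters across the depth of the network
  probe <- function(getw, setw, gval) {
    m1 <- setw(model, getw(model) + eps)
    m2 <- setw(model, getw(model) - eps)
    num <- (loss_at(m1) - loss_at(m2)) / (2 * eps)
    expect_equal(num, gval, tolerance = 1e-4)
  }
  probe(function(m) m$weights$conv1$w[1, 1, 1, 1],
        function(m, v) { m$weights$conv1$w[1, 1, 1, 1] <- v; m },
        g$conv1$w[1, 1, 1, 1])
  probe(function(m) m$weights$stages[[2]][[1]]$ws[1, 1, 2, 3],
        function(m, v) { m$weights$stages[[2]][[1]]$ws[1, 1, 2, 3] <- v; m },
        g$stages[[2]][[1]]$ws[1, 1, 2, 3])
  probe(function(m) m$weights$stages[[4]][[2]]$bn2$gamma[2],
        function(m, v) { m$weights$stages[[4]][[2]]$bn2$gamma[2] <- v; m },
        g$stages[[4]][[2]]$bn2$gamma[2])
  probe(function(m) m$weights$fc$b[2],
        function(m, v) { m$weights$fc$b[2] <- v; m },
        g$fc$b[2])
})

test_that("zeroing every branch reduces the trunk to a fixed conv1 transform", {
  set.seed(7)
  model <- zero_branches(build_resnet(in_channels = 2, width = 2))
  x <- array(rnorm(10 * 22 * 21 * 2), c(22, 21, 10, 2))
  fw1 <- freshfuse:::resnet_forward(model, x, train = TRUE)
  # plain modules pass activations through; only conv1 and the three
  # shortcut convolutions shape the logits. Perturbing a plain-module
  # branch weight has no effect once re-zeroed paths are removed:
  m2 <- model
  m2$weights$stages[[1]][[1]]$bn1$gamma[1] <- 5 # feeds a zero conv2, no effect
  fw2 <- freshfuse:::resnet_forward(m2, x, train = TRUE)
  expect_equal(fw1$logits, fw2$logits, tolerance = 1e-12)
})

test_that("training contracts: no-update limit, determinism, tie-breaking", {
  ds <- tiny_dataset(seed = 21)
  fused <- fuse_dataset(ds)
  # lr = 0, full batch: the recorded loss cannot move
  f0 <- resnet_rh(fused, ds$labels, width = 2, epochs = 4,
                  batch_size = 16, lr = 0,
                  split = list(train = 1:16, test = integer(0)), seed = 3)
  expect_equal(diff(range(f0$history$train_loss)), 0, tolerance = 1e-12)
  # fixed seed twice: identical history and weights
  f1 <- resnet_rh(fused, ds$labels, width = 2, epochs = 3, seed = 9,
                  train_fraction = 0.7)
  f2 <- resnet_rh(fused, ds$labels, width = 2, epochs = 3, seed = 9,
                  train_fraction = 0.7)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
  # prediction is argmax with lowest-index tie-breaking
  probs <- matrix(c(0.4, 0.4, 0.1, 0.1), 1)
  expect_equal(max.col(probs, ties.method = "first") - 1L, 0L)
  p <- predict(f1, fused$tensors[1:2, , , , drop = FALSE])
  expect_true(all(p %in% 0:3))
  expect_length(predict(f1, fused$tensors[1, , , ]), 1L)
  # a training split lacking class diversity errors
  expect_error(resnet_rh(fused, ds$labels, width = 2, epochs = 1,
                         split = list(train = 1:4, test = 5:16), seed = 1),
               "stratification error")
})

test_that("an easily separable dataset is fit to high training accuracy", {
  ds <- generate_dataset(generator_config(n_per_class = 8,
                                          rgb_size = c(44, 42), seed = 33))
  fused <- fuse_dataset(ds)
  fit <- resnet_rh(fused, ds$labels, width = 8, epochs = 12, batch_size = 16,
                   lr = 2e-3, split = list(train = 1:32, test = integer(0)),
                   seed = 4)
  expect_gt(tail(fit$history$train_acc, 1), 0.95)
})
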