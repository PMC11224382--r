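test_that("confusion tallies true-by-predicted counts", {
  perfect <- confusion(c(0, 1, 2, 3, 2), c(0, 1, 2, 3, 2))
  expect_equal(sum(perfect), 5)
  expect_equal(sum(diag(perfect)), 5)
  all0 <- confusion(c(0, 1, 2, 3), rep(0, 4))
  expect_equal(unname(colSums(all0)), c(4, 0, 0, 0))
  # random labels against a counting-loop oracle
  set.seed(12)
  t <- sample(0:3, 50, replace = TRUE)
  p <- sample(0:3, 50, replace = TRUE)
  got <- confusion(t, p)
  want <- matrix(0L, 4, 4)
  for (i in seq_along(t)) want[t[i] + 1, p[i] + 1] <- want[t[i] + 1, p[i] + 1] + 1L
  expect_equal(unclass(got), want, ignore_attr = TRUE)
  # invariant to permuting sample order
  o <- sample(50)
  expect_equal(unclass(confusion(t[o], p[o])), unclass(got))
  expect_error(confusion(c(0, 4), c(0, 1)), "label error")
})

test_that("metrics implement accuracy, one-vs-rest precision/recall, macro means", {
  d <- confusion(rep(0:3, 5), rep(0:3, 5))
  r <- metrics(d)
  expect_equal(r$accuracy, 1)
  expect_equal(r$macro_precision, 1)
  expect_equal(r$macro_recall, 1)
  expect_equal(r$macro_f1, 1)
  # two-class toy, hand-computed
  m <- matrix(c(5, 1, 2, 4), 2, 2, byrow = TRUE)
  r2 <- metrics(m)
  expect_equal(r2$accuracy, 9 / 12)
  expect_equal(r2$per_class$precision[1], 5 / 7)
  expect_equal(r2$per_class$recall[1], 5 / 6)
  expect_equal(r2$per_class$f1[1],
               2 * (5 / 7) * (5 / 6) / (5 / 7 + 5 / 6))
  # macro recall equals the mean row-normalised diagonal
  set.seed(13)
  u <- matrix(sample(0:9, 16, replace = TRUE), 4, 4) + diag(4)
  r3 <- metrics(u)
  expect_equal(r3$macro_recall, mean(diag(u) / rowSums(u)))
  # accuracy = micro precision = micro recall in single-label multiclass
  tp <- diag(u)
  expect_equal(r3$accuracy, sum(tp) / sum(u))
  expect_equal(sum(tp) / sum(colSums(u)), sum(tp) / sum(rowSums(u)))
  # never-predicted class gets precision 0 and is flagged
  z <- matrix(c(3, 0, 1, 0, 0, 0, 0, 0, 4), 3, 3, byrow = TRUE)
  z[, 2] <- 0
  rz <- metrics(z)
  expect_equal(rz$per_class$precision[2], 0)
  expect_true(1 %in% rz$zero_division_classes)
  expect_error(metrics(matrix(0, 4, 4)), "empty evaluation")
})

test_that("wilson_interval reproduces known bounds and the inversion oracle", {
  # the 95% interval for 97.6% on 125 test samples
  wi <- wilson_interval(125, 0.976, 0.95)
  expect_equal(round(wi[["lower"]], 4), 0.9318)
  expect_equal(round(wi[["upper"]], 4), 0.9918)
  # collapse at p_hat = 1: upper bound exactly 1
  expect_identical(wilson_interval(125, 1, 0.95)[["upper"]], 1)
  expect_identical(wilson_interval(125, 0, 0.95)[["lower"]], 0)
  # numeric score-test inversion oracle
  for (case in list(c(100, 0.5, 0.95), c(125, 0.976, 0.99),
                    c(30, 0.1, 0.9), c(10, 0.95, 0.95))) {
    got <- wilson_interval(case[1], case[2], case[3])
    want <- wilson_oracle(case[1], case[2], case[3])
    expect_equal(got[["lower"]], want[["lower"]], tolerance = 1e-6)
    expect_equal(got[["upper"]], want[["upper"]], tolerance = 1e-6)
  }
  expect_error(wilson_interval(100, 0.5, 1.2), "domain error")
})

test_that("wilson interval contains p_hat and narrows with n", {
  set.seed(14)
  for (i in 1:20) {
    p <- runif(1); n <- sample(5:500, 1)
    wi <- wilson_interval(n, p, 0.95)
    expect_true(wi[["lower"]] <= p && p <= wi[["upper"]])
    wi2 <- wilson_interval(4 * n, p, 0.95)
    expect_lt(wi2[["upper"]] - wi2[["lower"]], wi[["upper"]] - wi[["lower"]])
  }
})

test_that("percent_change computes signed percent from start and end", {
  expect_equal(round(percent_change(12.64, 7.22), 2), -42.88)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(1, 2), 100)
  expect_error(percent_change(0, 1), "domain error")
})
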