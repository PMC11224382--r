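# Classical baselines: decision tree (rpart, information gain), random
# forest (randomForest), AdaBoost (SAMME with depth-1 rpart stumps,
# implemented here -- the staged additive multi-class formulation), and
# k-nearest neighbours (class::knn).

#' Flatten image/spectral samples into a feature table
#'
#' Flattens each sample tensor to one feature row in a fixed order (rows,
#' then columns, then channels), consistent across the pipeline: a fused
#' `22 x 21 x 4` sample becomes a row of 1848 features, an RGB sample 1386,
#' a spectrum 462.
#'
#' @param x samples in any form accepted by [resnet_rh()], or an
#'   `n x d` matrix (returned as is).
#' @param labels optional class codes attached to the table.
#' @param source tag: `"rgb"`, `"hyperspectral"` or `"fusion"`.
#' @return object of class `"feature_table"`: list with `matrix`
#'   (`n x d`), `labels`, `source`.
#' @export
flatten_features <- function(x, labels = NULL, source = "fusion") {
  if (is.matrix(x)) {
    m <- x
  } else {
    xs <- as_tensor_stack(x)
    n <- dim(xs)[1]
    # row-major within each sample: channel-major, then rows, then columns
    m <- matrix(0, n, prod(dim(xs)[-1]))
    for (i in seq_len(n)) m[i, ] <- as.vector(xs[i, , , ])
  }
  if (anyNA(m)) stop("feature table contains missing values")
  structure(list(matrix = m, labels = labels, source = source),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d x %d, source %s>\n",
              nrow(x$matrix), ncol(x$matrix), x$source))
  invisible(x)
}

BASELINE_NAMES <- c("decision_tree", "random_forest", "adaboost", "knn")

#' Fit a baseline classifier
#'
#' @param name one of `"decision_tree"` (rpart, information-gain splits),
#'   `"random_forest"` (100 trees), `"adaboost"` (SAMME, 50 rounds of
#'   depth-2 weighted trees -- a binary stump cannot express 4-class
#'   structure, so the base learner has 4 leaves), `"knn"` (k = 5,
#'   Euclidean).
#' @param table a [flatten_features()] table with labels, or an `n x d`
#'   matrix paired with `labels`.
#' @param labels class codes 0--3 when `table` is a bare matrix.
#' @param seed RNG seed for the stochastic ensembles.
#' @param n_trees random-forest tree count.
#' @param boost_rounds AdaBoost rounds.
#' @param boost_depth AdaBoost base-tree depth (1 or 2).
#' @param k KNN neighbour count.
#' @return object of class `"freshness_baseline"` with a `predict` method.
#' @export
fit_baseline <- function(name, table, labels = NULL, seed = 1L,
                         n_trees = 100L, boost_rounds = 50L,
                         boost_depth = 2L, k = 5L) {
  if (!name %in% BASELINE_NAMES)
    stop(sprintf("unsupported model '%s'; use one of: %s", name,
                 paste(BASELINE_NAMES, collapse = ", ")))
  if (inherits(table, "feature_table")) {
    m <- table$matrix
    y <- if (is.null(labels)) table$labels else labels
  } else {
    m <- as.matrix(table)
    y <- labels
  }
  if (is.null(y)) stop("labels are required to fit a baseline")
  y <- as.integer(if (is.factor(y)) as.integer(as.character(y)) else y)
  stopifnot(nrow(m) == length(y))
  if (length(unique(y)) < 2L) stop("need at least 2 classes to fit")
  set.seed(seed)
  fit <- switch(name,
    decision_tree = {
      df <- as.data.frame(m)
      df$.y <- factor(y)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = "information"),
                   control = rpart::rpart.control(cp = 0, minsplit = 2,
                                                  xval = 0))
    },
    random_forest = randomForest::randomForest(m, factor(y), ntree = n_trees),
    adaboost = adaboost_fit(m, y, n_rounds = boost_rounds,
                            depth = boost_depth),
    knn = {
      if (k > nrow(m)) stop("k exceeds the number of training samples")
      list(train = m, y = y, k = k)
    })
  structure(list(name = name, fit = fit, classes = sort(unique(y))),
            class = "freshness_baseline")
}

# Exact weighted multi-class decision stump: for every feature, split
# points are scanned via per-class cumulative weight sums along the sorted
# order (precomputed once), minimising weighted Gini impurity (the
# misclassification count is not strictly concave and lets boosting
# oscillate between complementary splits). Each side of the winning split
# predicts its weighted-majority class.
stump_fit <- function(sorted_vals, ord, y1, w, kk) {
  n <- nrow(ord); d <- ncol(ord)
  # per-class cumulative weights along each feature's sorted order
  left <- vector("list", kk)
  tot <- numeric(kk)
  for (c in seq_len(kk)) {
    wc <- w * (y1 == c)
    tot[c] <- sum(wc)
    left[[c]] <- apply(matrix(wc[ord], n, d), 2, cumsum)
  }
  wl <- Reduce(`+`, left)
  wr <- sum(tot) - wl
  sq_l <- Reduce(`+`, lapply(left, function(L) L * L))
  sq_r <- Reduce(`+`, lapply(seq_len(kk),
                             function(c) (tot[c] - left[[c]])^2))
  err <- (wl - sq_l / pmax(wl, 1e-300)) + (wr - sq_r / pmax(wr, 1e-300))
  err <- err[-n, , drop = FALSE]                      # split after row k < n
  err[sorted_vals[-n, ] == sorted_vals[-1, ]] <- Inf  # ties: no threshold
  best <- arrayInd(which.min(err), dim(err))
  k <- best[1]; j <- best[2]
  cl <- which.max(vapply(left, function(L) L[k, j], numeric(1)))
  cr <- which.max(vapply(seq_len(kk), function(c) tot[c] - left[[c]][k, j],
                         numeric(1)))
  list(feature = j,
       threshold = (sorted_vals[k, j] + sorted_vals[k + 1, j]) / 2,
       class_left = cl, class_right = cr)
}

stump_predict <- function(st, m) {
  ifelse(m[, st$feature] <= st$threshold, st$class_left, st$class_right)
}

# sorted order and sorted values per feature, reused across boosting rounds
stump_precompute <- function(m) {
  n <- nrow(m)
  ord <- apply(m, 2, order)
  list(ord = ord,
       sv = matrix(m[ord + rep((seq_len(ncol(m)) - 1L) * n, each = n)],
                   n, ncol(m)))
}

weighted_majority <- function(y1, w, kk) {
  which.max(vapply(seq_len(kk), function(c) sum(w[y1 == c]), numeric(1)))
}

# Depth-2 weighted tree: a root stump plus one stump per side (4 leaves --
# enough to separate 4 classes, which a single binary stump cannot).
boost_tree_fit <- function(m, y1, w, kk, pre) {
  root <- tryCatch(stump_fit(pre$sv, pre$ord, y1, w, kk),
                   error = function(e) NULL)
  if (is.null(root) || !is.finite(root$threshold))
    return(list(leaf = weighted_majority(y1, w, kk)))
  side <- m[, root$feature] <= root$threshold
  kids <- list()
  for (s in c("TRUE", "FALSE")) {
    idx <- which(side == (s == "TRUE"))
    kid <- NULL
    if (length(idx) >= 4L && length(unique(y1[idx])) >= 2L) {
      ms <- m[idx, , drop = FALSE]
      kid <- tryCatch(stump_fit(stump_precompute(ms)$sv,
                                apply(ms, 2, order),
                                y1[idx], w[idx], kk),
                      error = function(e) NULL)
      if (!is.null(kid) && !is.finite(kid$threshold)) kid <- NULL
    }
    kids[[s]] <- if (is.null(kid))
      list(leaf = weighted_majority(y1[idx], w[idx], kk)) else kid
  }
  list(root = root, kids = kids)
}

boost_tree_predict <- function(tree, m) {
  n <- nrow(m)
  if (!is.null(tree$leaf)) return(rep(tree$leaf, n))
  side <- m[, tree$root$feature] <= tree$root$threshold
  out <- integer(n)
  for (s in c("TRUE", "FALSE")) {
    idx <- which(side == (s == "TRUE"))
    if (length(idx) == 0L) next
    k <- tree$kids[[s]]
    out[idx] <- if (!is.null(k$leaf)) k$leaf
    else ifelse(m[idx, k$feature] <= k$threshold, k$class_left, k$class_right)
  }
  out
}

# SAMME: forward staged additive modelling for K classes. Each round fits a
# weighted depth-`depth` tree, earns weight log((1-err)/err) + log(K-1),
# and re-weights misclassified samples; prediction is the weighted vote.
adaboost_fit <- function(m, y, n_rounds = 50L, depth = 2L) {
  n <- nrow(m)
  classes <- sort(unique(y))
  kk <- length(classes)
  y1 <- match(y, classes)
  pre <- stump_precompute(m)
  w <- rep(1 / n, n)
  trees <- list()
  alphas <- numeric(0)
  for (r in seq_len(n_rounds)) {
    tree <- if (depth >= 2L) boost_tree_fit(m, y1, w, kk, pre)
            else c(stump_fit(pre$sv, pre$ord, y1, w, kk), list(kids = NULL))
    pred <- if (depth >= 2L) boost_tree_predict(tree, m)
            else stump_predict(tree, m)
    miss <- pred != y1
    err <- sum(w[miss]) / sum(w)
    if (err >= 1 - 1 / kk) break       # no better than chance: stop
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(kk - 1)
    trees[[length(trees) + 1L]] <- tree
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
    if (err < 1e-9) break              # perfect learner: vote is decided
  }
  list(trees = trees, alphas = alphas, classes = classes, depth = depth)
}

adaboost_predict <- function(fit, m) {
  votes <- matrix(0, nrow(m), length(fit$classes))
  for (r in seq_along(fit$trees)) {
    pred <- if (fit$depth >= 2L) boost_tree_predict(fit$trees[[r]], m)
            else stump_predict(fit$trees[[r]], m)
    idx <- cbind(seq_len(nrow(m)), pred)
    votes[idx] <- votes[idx] + fit$alphas[r]
  }
  fit$classes[max.col(votes, ties.method = "first")]
}

#' Predict with a fitted baseline classifier
#'
#' @param object a [fit_baseline()] result.
#' @param newdata a [flatten_features()] table or `n x d` matrix.
#' @param ... unused.
#' @return integer class codes.
#' @export
predict.freshness_baseline <- function(object, newdata, ...) {
  m <- if (inherits(newdata, "feature_table")) newdata$matrix
       else as.matrix(newdata)
  switch(object$name,
    decision_tree = {
      p <- predict(object$fit, as.data.frame(m), type = "class")
      as.integer(as.character(p))
    },
    random_forest = as.integer(as.character(predict(object$fit, m))),
    adaboost = adaboost_predict(object$fit, m),
    knn = {
      p <- class::knn(object$fit$train, m, factor(object$fit$y),
                      k = object$fit$k)
      as.integer(as.character(p))
    })
}

#' @export
print.freshness_baseline <- function(x, ...) {
  cat(sprintf("<freshness_baseline: %s, classes %s>\n", x$name,
              paste(x$classes, collapse = ",")))
  invisible(x)
}
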