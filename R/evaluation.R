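# Evaluation: confusion matrices, accuracy / macro precision / recall / F1
# via one-vs-rest reduction, Wilson score intervals for the test accuracy,
# and the percent-change arithmetic used for the physicochemical traits.

#' Confusion matrix for multi-class predictions
#'
#' `counts[i, j]` is the number of samples with true class `i - 1`
#' predicted as class `j - 1` (rows = truth, columns = prediction).
#'
#' @param true_labels,predicted_labels class codes in `0..n_classes-1`.
#' @param n_classes number of classes (default 4).
#' @return integer matrix of class `"confusion_matrix"`.
#' @export
confusion <- function(true_labels, predicted_labels, n_classes = 4L) {
  t <- as.integer(true_labels); p <- as.integer(predicted_labels)
  if (length(t) != length(p)) stop("label vectors differ in length")
  if (any(t < 0 | t >= n_classes) || any(p < 0 | p >= n_classes))
    stop(sprintf("label error: labels must lie in 0..%d", n_classes - 1L))
  m <- matrix(0L, n_classes, n_classes,
              dimnames = list(true = 0:(n_classes - 1L),
                              predicted = 0:(n_classes - 1L)))
  for (i in seq_along(t)) m[t[i] + 1L, p[i] + 1L] <- m[t[i] + 1L, p[i] + 1L] + 1L
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, columns = predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is the trace over the total. Per-class precision, recall and
#' F1 use the one-vs-rest reduction (TP on the diagonal, FP down the
#' column, FN along the row); a class never predicted gets precision 0 by
#' convention and is flagged. The averaged metrics are macro (unweighted
#' class means), appropriate for the balanced storage-day design.
#'
#' @param m a [confusion()] matrix (or any square count matrix).
#' @return object of class `"eval_report"`: list with `accuracy`,
#'   `macro_precision`, `macro_recall`, `macro_f1`, `per_class` (data
#'   frame), `n`, `zero_division_classes`.
#' @export
metrics <- function(m) {
  m <- unclass(as.matrix(m))
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  n <- sum(m)
  if (n <= 0) stop("empty evaluation: confusion matrix sums to zero")
  k <- nrow(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(accuracy = sum(tp) / n,
                 macro_precision = mean(prec),
                 macro_recall = mean(rec),
                 macro_f1 = mean(f1),
                 per_class = data.frame(class = seq_len(k) - 1L,
                                        precision = prec, recall = rec,
                                        f1 = f1, support = rowSums(m)),
                 n = n,
                 zero_division_classes = which(tp + fp == 0) - 1L),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Accuracy %.4f | macro precision %.4f | recall %.4f | F1 %.4f (n = %d)\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1, x$n))
  print(x$per_class, row.names = FALSE, digits = 4)
  if (length(x$zero_division_classes) > 0)
    cat(sprintf("  note: class(es) %s never predicted; precision set to 0\n",
                paste(x$zero_division_classes, collapse = ", ")))
  invisible(x)
}

#' Wilson score confidence interval for a proportion
#'
#' Inverts the normal-approximation score test: centre
#' `(p + z^2/2n) / (1 + z^2/n)`, half-width
#' `z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`, with the two-sided
#' normal quantile `z` for the stated level and no continuity correction.
#' Well behaved for proportions near 0 or 1, which is why it is the
#' interval of choice for high test accuracies on small test sets.
#'
#' @param n number of trials (test samples).
#' @param p_hat observed proportion (test accuracy).
#' @param level confidence level in (0, 1), default 0.95.
#' @return named numeric `c(lower, upper)`, clamped to `[0, 1]`.
#' @examples
#' wilson_interval(125, 0.976) # about 0.9318 to 0.9918
#' @export
wilson_interval <- function(n, p_hat, level = 0.95) {
  if (n < 1) stop("n must be at least 1")
  if (p_hat < 0 || p_hat > 1) stop("p_hat must lie in [0, 1]")
  if (level <= 0 || level >= 1) stop("domain error: level must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  denom <- 1 + z^2 / n
  centre <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  # the interval collapses onto the boundary algebraically at p_hat 0 or 1
  lower <- if (p_hat == 0) 0 else max(0, centre - half)
  upper <- if (p_hat == 1) 1 else min(1, centre + half)
  c(lower = lower, upper = upper)
}

#' Signed percent change between two quantities
#'
#' `100 * (v_end - v_start) / v_start`; a negative value is reported in
#' the trait tables as a decrease rate of the same magnitude.
#'
#' @param v_start,v_end start and end values; `v_start` must be non-zero.
#' @return signed percent.
#' @examples
#' percent_change(12.64, 7.22) # -42.88: a 42.88% decrease
#' @export
percent_change <- function(v_start, v_end) {
  if (v_start == 0) stop("domain error: v_start must be non-zero")
  100 * (v_end - v_start) / v_start
}
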