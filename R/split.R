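#' Stratified train/test split
#'
#' Splits sample indices so the class proportions of the whole set carry
#' over to both subsets. The test-set size is the ceiling of
#' `(1 - train_fraction) * n` (so 416 samples at a 0.70 training fraction
#' give 125 test samples), distributed over the classes by largest
#' remainder with ties going to the lowest class code; membership within a
#' class is drawn from the current RNG stream.
#'
#' @param labels vector of class codes.
#' @param train_fraction fraction of samples used for training, in (0, 1).
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.7) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n <- length(labels)
  n_test <- as.integer(ceiling((1 - train_fraction) * n))
  classes <- sort(unique(labels))
  counts <- vapply(classes, function(k) sum(labels == k), integer(1))
  exact <- n_test * counts / n
  take <- floor(exact)
  rem <- n_test - sum(take)
  if (rem > 0) {
    # largest fractional remainders first; ties to the lowest class code
    ord <- order(-(exact - take), seq_along(classes))
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
  }
  test <- integer(0)
  for (i in seq_along(classes)) {
    idx <- which(labels == classes[i])
    if (take[i] >= length(idx))
      stop("stratification error: a class would vanish from the training split")
    test <- c(test, sample(idx, take[i]))
  }
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}
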