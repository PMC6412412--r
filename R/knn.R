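# Deterministic k-nearest-neighbour machinery used by the projection
# ensemble. Tie rules (fixed so runs are bit-reproducible):
#   * equidistant neighbours: lowest training index wins a slot;
#   * even-k split votes: class 1 iff the class-1 prior >= 0.5, else class 0.

# squared Euclidean cross-distances, rows of `a` x rows of `b`
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

# neighbour ordering per row of `d2` (stable: ties -> lowest column index)
neighbour_order <- function(d2, kmax) {
  out <- apply(d2, 1L, function(r) order(r)[seq_len(kmax)])
  if (kmax == 1L) matrix(out, ncol = 1L) else t(out)
}

vote_labels <- function(votes1, k, tie_class) {
  as.integer(ifelse(votes1 * 2 > k, 1L, ifelse(votes1 * 2 < k, 0L, tie_class)))
}

#' Leave-one-out error of a KNN classifier
#'
#' Fraction of points misclassified when each is predicted from the majority
#' vote of its `k` nearest Euclidean neighbours, excluding itself. This
#' estimate both selects `k` and ranks candidate projections in the ensemble.
#'
#' @param Z Numeric matrix, rows = samples (projected coordinates).
#' @param y 0/1 label vector.
#' @param k Neighbour count, `1 <= k < nrow(Z)`.
#' @return Error fraction in `[0, 1]`.
#' @export
knn_loo_error <- function(Z, y, k) {
  knn_loo_error_grid(as.matrix(Z), as.integer(y), k)[[1]]
}

# LOO errors for a whole k grid at once; one distance matrix, one sort.
knn_loo_error_grid <- function(Z, y, k_grid) {
  n <- length(y)
  if (any(k_grid >= n) || any(k_grid < 1L)) {
    abort(sprintf("k values must lie in [1, n - 1] = [1, %d].", n - 1L))
  }
  kmax <- max(k_grid)
  d2 <- cross_dist2(Z, Z)
  diag(d2) <- Inf                       # exclude self
  ord <- neighbour_order(d2, kmax)      # n x kmax
  lab <- matrix(y[ord], nrow = n)
  # n x kmax running class-1 vote counts
  cum <- if (kmax == 1L) lab else t(apply(lab, 1L, cumsum))
  tie_class <- as.integer(mean(y) >= 0.5)
  vapply(k_grid, function(k) {
    mean(vote_labels(cum[, k], k, tie_class) != y)
  }, numeric(1))
}

# hard KNN prediction of `test` from labelled `train` rows
knn_predict <- function(train, y, test, k, tie_class = as.integer(mean(y) >= 0.5)) {
  ord <- neighbour_order(cross_dist2(as.matrix(test), as.matrix(train)), k)
  lab <- matrix(y[ord], nrow = nrow(ord))
  vote_labels(rowSums(lab), k, tie_class)
}
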