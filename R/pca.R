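#' PCA reduction of feature tables
#'
#' The 400 spectral descriptors are correlated; PCA compresses them to `q`
#' orthogonal components (default 300) before classification. `pca_fit()`
#' performs mean-centred PCA via the singular value decomposition of the
#' centred data; `pca_transform()` projects a feature table onto the fitted
#' components. Fit PCA on training folds only and apply it to test folds to
#' avoid leakage; `kfold_cv()` does this by default.
#'
#' @param features A `sip_features` tibble (see [extract_features()]).
#' @param q Number of components to keep. Capped at
#'   `min(n_samples - 1, n_features)`; requesting more is an error.
#' @return `pca_fit()` returns a `sip_pca` object with fields `mean`
#'   (length-p centring vector), `components` (p x q orthonormal matrix),
#'   `explained_variance` (length q, non-increasing) and `q`.
#' @export
pca_fit <- function(features, q = 300L) {
  X <- features_matrix(features)
  cap <- min(nrow(X) - 1L, ncol(X))
  if (q > cap) {
    abort(sprintf("q = %d exceeds the maximum of min(n - 1, p) = %d.", q, cap))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = q)
  structure(
    list(mean = pc$center, components = unname(pc$rotation[, seq_len(q), drop = FALSE]),
         explained_variance = unname(pc$sdev[seq_len(q)]^2), q = as.integer(q)),
    class = "sip_pca")
}

#' @param model A fitted `sip_pca` object.
#' @rdname pca_fit
#' @export
pca_transform <- function(model, features) {
  stopifnot(inherits(model, "sip_pca"))
  X <- features_matrix(features)
  if (ncol(X) != length(model$mean)) {
    abort(sprintf("Feature count (%d) does not match the PCA model (%d).",
                  ncol(X), length(model$mean)))
  }
  Z <- sweep(X, 2L, model$mean) %*% model$components
  labels <- if (anyNA(features$label)) NULL else features$label
  new_features(Z, ids = features$id, labels = labels,
               extractor = attr(features, "extractor"), reduced = TRUE)
}

#' Default PCA dimension, capped for small data
#'
#' Returns `min(q, n - 1, p)` so the conventional 400-to-300 reduction
#' degrades gracefully on small synthetic runs.
#'
#' @param n,p Training sample and feature counts.
#' @param q Requested dimension (default 300).
#' @return An integer.
#' @export
pca_q_capped <- function(n, p, q = 300L) {
  as.integer(min(q, n - 1L, p))
}
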