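#' Gram matrix of a PSSM
#'
#' Collapses the length-dependent N x 20 PSSM to the length-independent
#' 20 x 20 Gram matrix `t(M) %*% M`, the common input to the spectral
#' descriptors. The result is symmetric positive semi-definite for any N.
#'
#' @param profile A [pssm_profile()].
#' @return A 20 x 20 numeric matrix.
#' @export
gram_matrix <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  crossprod(profile$matrix)
}

#' Spectral descriptors of a 20 x 20 matrix
#'
#' Each extractor maps a protein's 20 x 20 summary matrix to a fixed
#' length-400 descriptor vector:
#'
#' * `fft_features()` — modulus of the 2-D discrete Fourier transform, with a
#'   1/N normalization applied per axis (so the DC coefficient equals the
#'   matrix mean), flattened row-major. The primary extractor.
#' * `dct_features()` — orthonormal 2-D type-II discrete cosine transform,
#'   flattened row-major (preserves the Frobenius norm).
#' * `svd_features()` — for `A = U S V^T`, the row-major flattening of
#'   `U %*% diag(S)`.
#' * `cov_features()` — operates on the raw PSSM instead: the 20 x 20 sample
#'   covariance of its columns (denominator N - 1), flattened row-major.
#'
#' @param A A finite 20 x 20 numeric matrix (Gram matrix of a PSSM).
#' @return A numeric vector of length 400.
#' @export
fft_features <- function(A) {
  A <- check_square20(A)
  Fc <- stats::fft(A) / length(A)      # 1/N per axis = 1/400 overall
  as.vector(t(Mod(Fc)))                # row-major flatten
}

#' @rdname fft_features
#' @export
dct_features <- function(A) {
  A <- check_square20(A)
  C <- dct_basis(20L)
  as.vector(t(C %*% A %*% t(C)))
}

# orthonormal DCT-II basis matrix: row k, column t = c_k cos(pi (2t+1) k / 2n)
dct_basis <- function(n) {
  k <- 0:(n - 1L)
  C <- sqrt(2 / n) * cos(pi * outer(k, 2L * k + 1L) / (2L * n))
  C[1L, ] <- sqrt(1 / n)
  C
}

#' @rdname fft_features
#' @export
svd_features <- function(A) {
  A <- check_square20(A)
  s <- svd(A)
  as.vector(t(s$u %*% diag(s$d)))
}

#' @param profile A [pssm_profile()] with at least two positions.
#' @rdname fft_features
#' @export
cov_features <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  if (nrow(profile$matrix) < 2L) {
    abort("Column covariance needs a PSSM with at least 2 positions.")
  }
  as.vector(t(stats::cov(profile$matrix)))
}

check_square20 <- function(A) {
  A <- as.matrix(A)
  if (!all(dim(A) == c(20L, 20L)) || !all(is.finite(A))) {
    abort("Expected a finite 20 x 20 matrix.")
  }
  A
}

#' Build a feature table from PSSM profiles
#'
#' Applies one descriptor extractor to every profile and assembles the
#' samples-by-features table the classifiers consume: one row per protein,
#' columns `id`, `label` (0/1 or NA) and `f0001`..`f0400`.
#'
#' @param profiles List of [pssm_profile()] objects.
#' @param labels Optional 0/1 vector, one per profile.
#' @param extractor One of `"FFT"`, `"DCT"`, `"SVD"`, `"COV"`.
#' @return A tibble of class `sip_features`; the extractor name is stored in
#'   attribute `"extractor"` and `"reduced"` records whether PCA has been
#'   applied.
#' @export
extract_features <- function(profiles, labels = NULL,
                             extractor = c("FFT", "DCT", "SVD", "COV")) {
  extractor <- match.arg(extractor)
  if (inherits(profiles, "pssm_profile")) profiles <- list(profiles)
  fn <- switch(extractor,
               FFT = function(p) fft_features(gram_matrix(p)),
               DCT = function(p) dct_features(gram_matrix(p)),
               SVD = function(p) svd_features(gram_matrix(p)),
               COV = cov_features)
  X <- do.call(rbind, lapply(profiles, fn))
  ids <- vapply(profiles, function(p) p$protein_id, character(1))
  new_features(X, ids = ids, labels = labels, extractor = extractor,
               reduced = FALSE)
}

new_features <- function(X, ids, labels = NULL, extractor = "FFT",
                         reduced = FALSE) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) abort("Feature matrix contains non-finite entries.")
  if (is.null(labels)) {
    labels <- rep(NA_integer_, nrow(X))
  } else {
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) abort("`labels` must contain only 0 and 1.")
    if (length(labels) != nrow(X)) abort("One label per row is required.")
  }
  colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  out <- dplyr::bind_cols(tibble::tibble(id = as.character(ids), label = labels),
                          tibble::as_tibble(X))
  attr(out, "extractor") <- extractor
  attr(out, "reduced") <- reduced
  class(out) <- c("sip_features", class(out))
  out
}

# numeric matrix of the f#### columns
features_matrix <- function(features) {
  cols <- grep("^f[0-9]+$", names(features), value = TRUE)
  if (length(cols) == 0L) abort("No feature columns (f0001, ...) found.")
  as.matrix(features[, cols])
}

features_labels <- function(features, required = TRUE) {
  y <- features$label
  if (required && (is.null(y) || anyNA(y))) {
    abort("This operation requires complete 0/1 labels.")
  }
  as.integer(y)
}

#' Read and write feature tables as TSV
#'
#' @param features A `sip_features` tibble.
#' @param path TSV file path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns a `sip_features` tibble.
#' @export
write_features <- function(features, path) {
  df <- as.data.frame(features)
  attr(df, "extractor") <- NULL
  utils::write.table(
    cbind(extractor = attr(features, "extractor"), df),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  labels <- if (all(is.na(df$label))) NULL else df$label
  new_features(as.matrix(df[, grep("^f[0-9]+$", names(df))]),
               ids = df$id, labels = labels,
               extractor = as.character(df$extractor[[1]]))
}
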