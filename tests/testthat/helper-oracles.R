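# Independent brute-force oracles. These deliberately use naive loops so
# they share no code path with the package implementations they check.

# 2-D DFT modulus by explicit quadruple loop, 1/N normalization per axis
naive_dft2_mod <- function(A) {
  n <- nrow(A)
  out <- matrix(0, n, n)
  for (u in 0:(n - 1)) for (v in 0:(n - 1)) {
    acc <- 0 + 0i
    for (s in 0:(n - 1)) for (t in 0:(n - 1)) {
      acc <- acc + A[s + 1, t + 1] * exp(-2i * pi * (u * s + v * t) / n)
    }
    out[u + 1, v + 1] <- Mod(acc / n^2)
  }
  out
}

# orthonormal 2-D DCT-II by explicit cosine sums
naive_dct2 <- function(A) {
  n <- nrow(A)
  cf <- function(k) if (k == 0) sqrt(1 / n) else sqrt(2 / n)
  out <- matrix(0, n, n)
  for (u in 0:(n - 1)) for (v in 0:(n - 1)) {
    acc <- 0
    for (s in 0:(n - 1)) for (t in 0:(n - 1)) {
      acc <- acc + A[s + 1, t + 1] *
        cos(pi * (2 * s + 1) * u / (2 * n)) * cos(pi * (2 * t + 1) * v / (2 * n))
    }
    out[u + 1, v + 1] <- cf(u) * cf(v) * acc
  }
  out
}

# leave-one-out KNN error by double loop; ties: equidistant -> lowest index,
# split votes -> class with prior >= 0.5
brute_loo_knn <- function(Z, y, k) {
  n <- nrow(Z)
  tie_class <- as.integer(mean(y) >= 0.5)
  wrong <- 0
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n)) {
      if (j != i) d[j] <- sum((Z[i, ] - Z[j, ])^2)
    }
    nb <- order(d)[seq_len(k)]
    v <- sum(y[nb])
    pred <- if (2 * v > k) 1L else if (2 * v < k) 0L else tie_class
    if (pred != y[i]) wrong <- wrong + 1
  }
  wrong / n
}

# plain KNN prediction by double loop (reference for the degeneracy check)
brute_knn_predict <- function(train, y, test, k, tie_class = as.integer(mean(y) >= 0.5)) {
  vapply(seq_len(nrow(test)), function(i) {
    d <- vapply(seq_len(nrow(train)), function(j) sum((test[i, ] - train[j, ])^2),
                numeric(1))
    v <- sum(y[order(d)[seq_len(k)]])
    if (2 * v > k) 1L else if (2 * v < k) 0L else tie_class
  }, integer(1))
}

# Mann-Whitney concordance (ties count one half)
mw_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# random profile with a permuted residue order, for round-trip tests
random_profile <- function(n = 12, id = "p1", permute_order = FALSE) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ord <- if (permute_order) sample(aa) else aa
  m <- matrix(round(rnorm(n * 20), 3), nrow = n)
  pssm_profile(m, paste(sample(aa, n, replace = TRUE), collapse = ""),
               protein_id = id, residue_order = paste(ord, collapse = ""))
}

# small labelled feature tibble from gaussian clusters (well separated when
# delta is large)
cluster_features <- function(n_per = 20, p = 8, delta = 4, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * p), ncol = p),
               matrix(rnorm(n_per * p, mean = delta), ncol = p))
    sipfft:::new_features(X, ids = sprintf("s%03d", seq_len(2 * n_per)),
                          labels = rep(c(0L, 1L), each = n_per))
  })
}
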