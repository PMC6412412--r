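#' Configuration of the random-projection ensemble
#'
#' The ensemble trains `B1` KNN base learners, each on a low-dimensional
#' random linear projection of the features. For every learner, `B2`
#' candidate projections are drawn and the one whose KNN classifier attains
#' the smallest leave-one-out error (minimised over `k_grid`) is kept, so the
#' `B1 * B2` candidates form `B1` non-overlapping selection blocks.
#'
#' @param B1 Ensemble size: number of selected projections (default 10).
#' @param B2 Candidate projections per selection block (default 30).
#' @param q Projected dimension (default 5); the projection literature uses
#'   small `q`, and the descriptors concentrate their class signal in few
#'   directions.
#' @param k_grid Candidate neighbour counts for the KNN base learner
#'   (default `seq(1, 40, by = 3)`).
#' @param law Projection law: `"gaussian"` (i.i.d. normal columns rescaled to
#'   the unit sphere), `"bernoulli"` (+1/-1 entries, columns rescaled to unit
#'   norm), or `"identity"` (no projection; a testing hook requiring
#'   `q = n_features`).
#' @return An `rp_config` list.
#' @export
rp_config <- function(B1 = 10L, B2 = 30L, q = 5L,
                      k_grid = seq(1L, 40L, by = 3L),
                      law = c("gaussian", "bernoulli", "identity")) {
  law <- match.arg(law)
  stopifnot(B1 >= 1L, B2 >= 1L, q >= 1L, all(k_grid >= 1L))
  structure(list(B1 = as.integer(B1), B2 = as.integer(B2), q = as.integer(q),
                 k_grid = as.integer(k_grid), law = law),
            class = "rp_config")
}

#' Draw one random projection matrix
#'
#' Samples a `q x n` matrix from the chosen law and rescales every column to
#' unit l2 norm, so projection never inflates coordinates. Draws consume the
#' current RNG stream, making whole-model fits reproducible from one seed.
#'
#' @param n Input (feature) dimension.
#' @param q Output dimension.
#' @param law `"gaussian"`, `"bernoulli"`, or `"identity"` (requires
#'   `q == n`).
#' @return A `q x n` matrix with unit-norm columns.
#' @export
sample_projection <- function(n, q, law = "gaussian") {
  stopifnot(n >= 1L, q >= 1L)
  R <- switch(law,
    gaussian = matrix(stats::rnorm(q * n), nrow = q),
    bernoulli = matrix(sample(c(-1, 1), q * n, replace = TRUE), nrow = q),
    identity = {
      if (q != n) abort("The identity projection hook requires q == n.")
      diag(n)
    },
    abort(sprintf("Unknown projection law: '%s'.", law))
  )
  norms <- sqrt(colSums(R^2))
  sweep(R, 2L, norms, "/")
}

# one selection block: draw B2 candidates, keep the (projection, k) pair with
# the smallest LOO error; ties -> earliest candidate, then smallest k
select_member <- function(X, y, cfg) {
  best <- NULL
  for (b in seq_len(cfg$B2)) {
    R <- sample_projection(ncol(X), cfg$q, cfg$law)
    Z <- X %*% t(R)
    errs <- knn_loo_error_grid(Z, y, cfg$k_grid)
    i <- which.min(errs)                 # ties -> smallest k (grid sorted)
    if (is.null(best) || errs[[i]] < best$loo_error) {
      best <- list(R = R, k = cfg$k_grid[[i]], loo_error = errs[[i]],
                   Z_train = Z, candidate = b)
    }
  }
  best
}

#' Fit the random-projection KNN ensemble
#'
#' Runs `B1` independent selection blocks (see [rp_config()]), storing for
#' each the winning projection, its neighbour count and the projected
#' training set. The voting threshold `alpha` is the training prevalence of
#' class 1 (the prior probability of a positive), so on undersampled
#' balanced data the ensemble behaves like majority voting while on
#' imbalanced data a minority of positive votes can already flag a positive.
#'
#' @param features A labelled `sip_features` tibble.
#' @param config An [rp_config()].
#' @param seed Optional integer; when given, the fit is reproducible in
#'   isolation. When `NULL`, draws consume the caller's RNG stream.
#' @return An `rp_ensemble` model.
#' @export
rp_fit <- function(features, config = rp_config(), seed = NULL) {
  if (!is.null(seed)) local_seed(seed)
  X <- features_matrix(features)
  y <- features_labels(features)
  if (length(unique(y)) < 2L) abort("Training data must contain both classes.")
  if (max(config$k_grid) >= nrow(X)) {
    abort("n_train must exceed max(k_grid); reduce the k grid or add samples.")
  }
  members <- lapply(seq_len(config$B1), function(i) select_member(X, y, config))
  structure(
    list(config = config, members = members, train_labels = y,
         alpha = mean(y == 1L), n_features = ncol(X),
         extractor = attr(features, "extractor")),
    class = "rp_ensemble")
}

#' Ensemble vote fraction
#'
#' For each sample, the fraction of the `B1` member classifiers voting class
#' 1; each member classifies by KNN (its selected `k`) in its own projected
#' space. This is the model's continuous score and is used for ROC curves.
#'
#' @param model An `rp_ensemble` fit.
#' @param features A `sip_features` tibble with the training feature
#'   dimension.
#' @return Numeric vector in `[0, 1]`, one entry per row.
#' @export
vote_fraction <- function(model, features) {
  stopifnot(inherits(model, "rp_ensemble"))
  X <- features_matrix(features)
  if (ncol(X) != model$n_features) {
    abort(sprintf("Feature count (%d) does not match the model (%d).",
                  ncol(X), model$n_features))
  }
  tie_class <- as.integer(model$alpha >= 0.5)
  votes <- vapply(model$members, function(m) {
    knn_predict(m$Z_train, model$train_labels, X %*% t(m$R), m$k, tie_class)
  }, integer(nrow(X)))
  if (nrow(X) == 1L) votes <- matrix(votes, nrow = 1L)
  rowMeans(votes)
}

#' Predict class labels from the ensemble
#'
#' A sample is called positive when its vote fraction strictly exceeds the
#' data-driven threshold `alpha` (the training prevalence).
#'
#' @param object An `rp_ensemble` fit.
#' @param features A `sip_features` tibble.
#' @param type `"class"` for 0/1 labels, `"vote"` for the vote fraction.
#' @param ... Unused.
#' @return Integer 0/1 vector or numeric vote fractions.
#' @export
predict.rp_ensemble <- function(object, features, type = c("class", "vote"), ...) {
  type <- match.arg(type)
  v <- vote_fraction(object, features)
  if (type == "vote") v else as.integer(v > object$alpha)
}

#' @export
print.rp_ensemble <- function(x, ...) {
  cat(sprintf(
    "<rp_ensemble> B1 = %d members (blocks of B2 = %d), q = %d, law = %s\n",
    x$config$B1, x$config$B2, x$config$q, x$config$law))
  cat(sprintf("  n_train = %d, alpha (vote threshold) = %.4f, mean LOO error = %.4f\n",
              length(x$train_labels), x$alpha,
              mean(vapply(x$members, `[[`, numeric(1), "loo_error"))))
  invisible(x)
}

#' Tidy a fitted random-projection ensemble
#'
#' @param x An `rp_ensemble` fit.
#' @param ... Unused.
#' @return One row per ensemble member: its selected neighbour count, its
#'   leave-one-out error, and the index of the winning candidate within its
#'   selection block.
#' @method tidy rp_ensemble
#' @export
tidy.rp_ensemble <- function(x, ...) {
  tibble::tibble(
    member = seq_along(x$members),
    k = vapply(x$members, `[[`, numeric(1), "k"),
    loo_error = vapply(x$members, `[[`, numeric(1), "loo_error"),
    candidate = vapply(x$members, `[[`, numeric(1), "candidate"))
}

#' @rdname tidy.rp_ensemble
#' @return `glance()`: a one-row summary (ensemble shape, voting threshold,
#'   mean member LOO error).
#' @method glance rp_ensemble
#' @export
glance.rp_ensemble <- function(x, ...) {
  tibble::tibble(
    B1 = x$config$B1, B2 = x$config$B2, q = x$config$q, law = x$config$law,
    n_train = length(x$train_labels), alpha = x$alpha,
    mean_loo_error = mean(vapply(x$members, `[[`, numeric(1), "loo_error")))
}

#' Serialize a fitted ensemble to JSON
#'
#' Stores projections, projected training sets, labels and configuration so a
#' reloaded model gives identical predictions.
#'
#' @param model An `rp_ensemble` fit.
#' @param path Output JSON path.
#' @return `path` invisibly; `read_rp_model()` returns the model.
#' @export
write_rp_model <- function(model, path) {
  stopifnot(inherits(model, "rp_ensemble"))
  payload <- list(
    config = unclass(model$config),
    alpha = model$alpha, n_features = model$n_features,
    extractor = model$extractor, train_labels = model$train_labels,
    members = lapply(model$members, function(m) {
      list(R = m$R, k = m$k, loo_error = m$loo_error, Z_train = m$Z_train,
           candidate = m$candidate)
    }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_rp_model
#' @export
read_rp_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  members <- lapply(p$members, function(m) {
    list(R = as.matrix(m$R), k = m$k, loo_error = m$loo_error,
         Z_train = as.matrix(m$Z_train), candidate = m$candidate)
  })
  cfg <- rp_config(B1 = p$config$B1, B2 = p$config$B2, q = p$config$q,
                   k_grid = p$config$k_grid, law = p$config$law)
  structure(list(config = cfg, members = members,
                 train_labels = as.integer(p$train_labels),
                 alpha = p$alpha, n_features = p$n_features,
                 extractor = p$extractor),
            class = "rp_ensemble")
}

# run code with a temporary RNG seed, restoring the caller's stream
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  withr::defer(
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }, envir = env)
  invisible(seed)
}
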