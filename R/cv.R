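#' Stratified fold assignment
#'
#' Randomly assigns each row to one of `n_folds` test folds, stratified by
#' label so per-fold class prevalence differs from the global prevalence by
#' less than one sample.
#'
#' @param y 0/1 label vector; each class must have at least `n_folds`
#'   members.
#' @param n_folds Number of folds (>= 2).
#' @return Integer vector of fold ids in `1..n_folds`.
#' @export
stratified_folds <- function(y, n_folds = 5L) {
  if (n_folds < 2L) abort("`n_folds` must be at least 2.")
  if (any(table(y) < n_folds)) {
    abort("Each class needs at least `n_folds` samples to stratify.")
  }
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

#' Aggregate per-fold metrics into mean and sample SD
#'
#' The cross-validation summary convention: each metric is averaged
#' arithmetically across folds and its spread reported as the sample
#' standard deviation (n - 1 denominator). Non-finite fold values (e.g. a
#' sensitivity with no positives in the fold) are dropped with a warning.
#'
#' @param per_fold Tibble of per-fold metric values; all numeric columns
#'   except `fold` are aggregated, and a `model` column, if present, groups
#'   the aggregation.
#' @return A tibble with columns `metric`, `mean`, `sd` (plus `model` when
#'   grouped).
#' @export
aggregate_folds <- function(per_fold) {
  num_cols <- setdiff(names(per_fold)[vapply(per_fold, is.numeric, logical(1))],
                      "fold")
  long <- tidyr::pivot_longer(per_fold, dplyr::all_of(num_cols),
                              names_to = "metric", values_to = "value")
  grp <- intersect("model", names(long))
  out <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "metric")))) |>
    dplyr::summarise(
      n_dropped = sum(!is.finite(.data$value)),
      mean = mean(.data$value[is.finite(.data$value)]),
      sd = stats::sd(.data$value[is.finite(.data$value)]),
      .groups = "drop")
  if (any(out$n_dropped > 0)) {
    warn(sprintf("Dropped %d non-finite fold value(s) from averaging.",
                 sum(out$n_dropped)))
  }
  out$metric <- factor(out$metric, levels = unique(long$metric))
  dplyr::select(dplyr::arrange(out, .data$metric), -"n_dropped")
}

#' Stratified k-fold cross-validation of the SIP classifiers
#'
#' Splits the labelled feature table into stratified folds and, for each
#' fold, fits PCA and the requested classifier(s) on the training folds and
#' evaluates on the held-out fold. When both arms are requested they share
#' the identical fold assignment, so comparisons are paired. PCA is
#' leakage-safe by default (fit on training folds only); `pca_global = TRUE`
#' fits it once on the full table instead.
#'
#' @param features A labelled `sip_features` tibble (raw 400-feature
#'   descriptors).
#' @param models Character subset of `c("rp", "svm")`.
#' @param n_folds Number of folds (default 5).
#' @param rp An [rp_config()] for the projection-ensemble arm.
#' @param svm An [svm_config()] for the SVM arm.
#' @param pca_q Target PCA dimension (default 300, capped at
#'   `min(n_train - 1, n_features)`).
#' @param use_pca Apply PCA before classification (default `TRUE`).
#' @param pca_global Fit PCA on the full table rather than per training
#'   split.
#' @param seed Integer seed; the whole run (folds, projections,
#'   undersampling upstream) is reproducible from it.
#' @return A `sip_cv` object: `per_fold` metrics, aggregated `summary`
#'   (mean and sample SD), per-sample `predictions`, and the run settings.
#' @export
kfold_cv <- function(features, models = "rp", n_folds = 5L,
                     rp = rp_config(), svm = svm_config(),
                     pca_q = 300L, use_pca = TRUE, pca_global = FALSE,
                     seed = 1L) {
  models <- match.arg(models, c("rp", "svm"), several.ok = TRUE)
  local_seed(seed)
  y <- features_labels(features)
  folds <- stratified_folds(y, n_folds)
  p <- ncol(features_matrix(features))

  global_pca <- if (use_pca && pca_global) {
    pca_fit(features, pca_q_capped(nrow(features), p, pca_q))
  }

  results <- purrr::map_dfr(seq_len(n_folds), function(f) {
    tr <- features[folds != f, ]; te <- features[folds == f, ]
    class(tr) <- class(te) <- class(features)
    attr(tr, "extractor") <- attr(te, "extractor") <- attr(features, "extractor")
    if (use_pca) {
      pca <- if (pca_global) global_pca else {
        pca_fit(tr, pca_q_capped(nrow(tr), p, pca_q))
      }
      tr <- pca_transform(pca, tr); te <- pca_transform(pca, te)
    }
    y_te <- features_labels(te)
    purrr::map_dfr(models, function(m) {
      if (m == "rp") {
        fit <- rp_fit(tr, rp)
        score <- vote_fraction(fit, te)
        pred <- as.integer(score > fit$alpha)
      } else {
        fit <- train_svm(tr, svm)
        score <- predict(fit, te, type = "score")
        pred <- predict(fit, te, type = "class")
      }
      tibble::tibble(model = m, fold = f, id = te$id, y = y_te,
                     score = score, pred = pred)
    })
  })

  per_fold <- results |>
    dplyr::group_by(.data$model, .data$fold) |>
    dplyr::summarise(
      metric_set(confusion(.data$y, .data$pred)),
      auc = auc(roc_curve(.data$y, .data$score)),
      .groups = "drop")

  structure(
    list(per_fold = per_fold, summary = aggregate_folds(per_fold),
         predictions = results, n_folds = as.integer(n_folds),
         models = models, seed = as.integer(seed),
         use_pca = use_pca, pca_global = pca_global),
    class = "sip_cv")
}

#' @export
print.sip_cv <- function(x, ...) {
  cat(sprintf("<sip_cv> %d-fold stratified cross-validation (seed %d)\n",
              x$n_folds, x$seed))
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "sd"))
  for (i in seq_len(nrow(wide))) {
    cat(sprintf("  %-4s", wide$model[[i]]))
    for (m in c("acc", "sen", "spe", "mcc", "bacc")) {
      cat(sprintf("  %s %5.2f +/- %4.2f", toupper(m),
                  100 * wide[[paste0("mean_", m)]][[i]],
                  100 * wide[[paste0("sd_", m)]][[i]]))
    }
    cat(sprintf("  AUC %.4f\n", wide$mean_auc[[i]]))
  }
  invisible(x)
}

#' Tidy methods for cross-validation reports
#'
#' `tidy()` returns the per-fold metric table; `glance()` one row per model
#' with fold-averaged metrics and their sample SDs.
#'
#' @param x A `sip_cv` object.
#' @param ... Unused.
#' @method tidy sip_cv
#' @export
tidy.sip_cv <- function(x, ...) x$per_fold

#' @rdname tidy.sip_cv
#' @method glance sip_cv
#' @export
glance.sip_cv <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean", "sd"),
                     names_glue = "{metric}_{.value}")
}

#' Write a cross-validation report
#'
#' `write_cv_json()` dumps the full report; `cv_markdown()` renders a
#' markdown table (per-fold rows plus an Average row, metrics as
#' percentages in the order Acc, Sen, Spe, MCC, B_Acc).
#'
#' @param cv A `sip_cv` object.
#' @param path Output path.
#' @return The path (JSON) or a character vector of markdown lines.
#' @export
write_cv_json <- function(cv, path) {
  jsonlite::write_json(
    list(per_fold = cv$per_fold, summary = cv$summary, n_folds = cv$n_folds,
         models = cv$models, seed = cv$seed),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cv_json
#' @export
cv_markdown <- function(cv) {
  cols <- c("acc", "sen", "spe", "mcc", "bacc")
  out <- c("| Model | Fold | Acc. (%) | Sen. (%) | Spe. (%) | MCC (%) | B_Acc. (%) | AUC |",
           "|---|---|---|---|---|---|---|---|")
  for (m in cv$models) {
    pf <- dplyr::filter(cv$per_fold, .data$model == m)
    for (i in seq_len(nrow(pf))) {
      out <- c(out, sprintf("| %s | %d | %s | %.4f |", m, pf$fold[[i]],
                            paste(sprintf("%.2f", 100 * unlist(pf[i, cols])),
                                  collapse = " | "),
                            pf$auc[[i]]))
    }
    sm <- dplyr::filter(cv$summary, .data$model == m)
    fmt <- vapply(cols, function(cc) {
      r <- sm[sm$metric == cc, ]
      sprintf("%.2f ± %.2f", 100 * r$mean, 100 * r$sd)
    }, character(1))
    out <- c(out, sprintf("| %s | Average | %s | %.4f |", m,
                          paste(fmt, collapse = " | "),
                          sm$mean[sm$metric == "auc"]))
  }
  out
}

#' Plot methods
#'
#' `autoplot()` on a `sip_roc` draws the ROC curve; on a `sip_cv` it draws
#' per-fold ROC curves for every model arm.
#'
#' @param object A `sip_roc` or `sip_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sip_roc
#' @export
autoplot.sip_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.4f)", auc(object)))
}

#' @rdname autoplot.sip_roc
#' @method autoplot sip_cv
#' @export
autoplot.sip_cv <- function(object, ...) {
  curves <- object$predictions |>
    dplyr::group_by(.data$model, .data$fold) |>
    dplyr::group_modify(~ roc_curve(.x$y, .x$score)) |>
    dplyr::ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr,
                                       group = .data$fold)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(alpha = 0.7) +
    ggplot2::facet_wrap(~ model) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("%d-fold cross-validated ROC", object$n_folds))
}
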