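#' Confusion counts for binary predictions
#'
#' @param y_true,y_pred 0/1 vectors of equal length.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L) {
    abort("`y_true` and `y_pred` must have equal, positive length.")
  }
  if (!all(c(y_true, y_pred) %in% c(0, 1))) {
    abort("Labels and predictions must be 0/1.")
  }
  tibble::tibble(
    tp = sum(y_true == 1 & y_pred == 1),
    fp = sum(y_true == 0 & y_pred == 1),
    tn = sum(y_true == 0 & y_pred == 0),
    fn = sum(y_true == 1 & y_pred == 0))
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy, sensitivity (recall on positives), specificity,
#' Matthews correlation coefficient and balanced accuracy
#' `(sensitivity + specificity) / 2`. Degenerate denominators: MCC with a
#' zero product denominator is defined as 0; sensitivity or specificity with
#' an empty class is `NaN` (and excluded, with a warning, from fold
#' averaging).
#'
#' @param counts A one-row tibble from [confusion()] (or any list with
#'   `tp`, `fp`, `tn`, `fn`).
#' @return A one-row tibble: `acc`, `sen`, `spe`, `mcc`, `bacc` (proportions,
#'   not percentages).
#' @export
metric_set <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  total <- tp + fp + tn + fn
  if (total <= 0) abort("Confusion counts sum to zero.")
  sen <- if ((tp + fn) == 0) NaN else tp / (tp + fn)
  spe <- if ((tn + fp) == 0) NaN else tn / (tn + fp)
  denom <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  tibble::tibble(acc = (tp + tn) / total, sen = sen, spe = spe,
                 mcc = mcc, bacc = (sen + spe) / 2)
}

#' ROC curve from continuous scores
#'
#' Sweeps every distinct score as a threshold `t`, calling a sample positive
#' iff `score > t` (the same strict inequality the ensemble's vote threshold
#' uses), and returns the operating points sorted by false-positive rate,
#' anchored at (0, 0) and (1, 1).
#'
#' @param y_true 0/1 vector containing both classes.
#' @param scores Numeric score vector (higher = more positive).
#' @return A `sip_roc` tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(y_true, scores) {
  if (length(unique(y_true)) < 2L) {
    abort("ROC needs both classes present in `y_true`.")
  }
  stopifnot(length(y_true) == length(scores), all(y_true %in% c(0, 1)))
  np <- sum(y_true == 1); nn <- sum(y_true == 0)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- purrr::map_dfr(th, function(t) {
    pred <- scores > t
    tibble::tibble(threshold = t,
                   fpr = sum(pred & y_true == 0) / nn,
                   tpr = sum(pred & y_true == 1) / np)
  })
  out <- pts |>
    dplyr::arrange(.data$fpr, .data$tpr) |>
    dplyr::distinct(.data$fpr, .data$tpr, .keep_all = TRUE)
  class(out) <- c("sip_roc", class(out))
  out
}

#' Area under a ROC curve (trapezoidal rule)
#'
#' @param roc A `sip_roc` tibble from [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(roc) {
  stopifnot(all(c("fpr", "tpr") %in% names(roc)))
  x <- roc$fpr; y <- roc$tpr
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Balance a labelled feature table by undersampling
#'
#' Keeps every minority-class sample and a uniform random subset of the
#' majority class of the same size, then shuffles the row order. This is how
#' the heavily imbalanced SIP datasets (e.g. 1441 positives vs 15,938
#' negatives in the human set) are balanced before cross-validation.
#'
#' @param features A labelled `sip_features` tibble.
#' @param seed Optional integer seed; `NULL` uses the caller's RNG stream.
#' @return A balanced `sip_features` tibble.
#' @export
undersample <- function(features, seed = NULL) {
  if (!is.null(seed)) local_seed(seed)
  y <- features_labels(features)
  if (length(unique(y)) < 2L) abort("Undersampling needs both classes present.")
  counts <- table(y)
  minority <- as.integer(names(counts)[which.min(counts)])
  n_min <- min(counts)
  keep_min <- which(y == minority)
  keep_maj <- sample(which(y != minority), n_min)
  idx <- sample(c(keep_min, keep_maj))
  out <- features[idx, ]
  attr(out, "extractor") <- attr(features, "extractor")
  attr(out, "reduced") <- attr(features, "reduced")
  class(out) <- unique(c("sip_features", class(out)))
  out
}
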