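#' Published SIP benchmark results shipped with the package
#'
#' Reference cross-validation results for sequence-based SIP prediction on
#' the curated human (1441 positives / 15,938 negatives) and yeast (710 /
#' 5511) benchmark datasets, as published: per-fold metrics for the
#' RP-on-FFT-features classifier and its SVM comparison arm
#' (`benchmark_fold_metrics()`), and the reported summary rows — fold
#' averages with sample SDs, the feature-extractor comparison, and earlier
#' methods — in `benchmark_summary_metrics()`. All values are percentages as
#' printed. They are reference points for the metric-aggregation arithmetic,
#' not outputs of this package.
#'
#' @return A tibble. Fold metrics: `dataset`, `model`, `fold`, `acc`, `sen`,
#'   `spe`, `mcc`, `bacc` (`bacc` is `NA` where the source table lacked it).
#'   Summary metrics: `dataset`, `model`, and `<metric>_mean` /
#'   `<metric>_sd` columns (`sd` is `NA` for single-value rows).
#' @export
benchmark_fold_metrics <- function() {
  tibble::as_tibble(utils::read.delim(
    system.file("extdata", "benchmark_fold_metrics.tsv", package = "sipfft")))
}

#' @rdname benchmark_fold_metrics
#' @export
benchmark_summary_metrics <- function() {
  tibble::as_tibble(utils::read.delim(
    system.file("extdata", "benchmark_summary_metrics.tsv", package = "sipfft")))
}
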