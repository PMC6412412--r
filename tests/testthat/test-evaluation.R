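test_that("confusion counts match an independent tally", {
  expect_equal(confusion(c(1, 0, 1, 0), c(1, 0, 1, 0)),
               tibble::tibble(tp = 2L, fp = 0L, tn = 2L, fn = 0L),
               ignore_attr = TRUE)
  y <- c(1, 0, 1, 0)
  expect_equal(unlist(confusion(y, 1 - y)[c("tp", "tn")]), c(tp = 0L, tn = 0L),
               ignore_attr = TRUE)

  set.seed(89)
  yt <- rbinom(200, 1, 0.4); yp <- rbinom(200, 1, 0.5)
  cc <- confusion(yt, yp)
  tally <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  for (i in 1:200) {
    key <- if (yt[i] == 1 && yp[i] == 1) "tp" else if (yt[i] == 0 && yp[i] == 1) "fp"
           else if (yt[i] == 0 && yp[i] == 0) "tn" else "fn"
    tally[key] <- tally[key] + 1
  }
  expect_equal(unlist(cc), tally, ignore_attr = TRUE)
  expect_equal(sum(unlist(cc)), 200)

  expect_error(confusion(c(1, 0), c(1, 0, 1)), "equal")
  expect_error(confusion(c(1, 2), c(1, 0)), "0/1")
})

test_that("the five metrics follow their defining formulas", {
  perfect <- metric_set(list(tp = 50, fp = 0, tn = 50, fn = 0))
  expect_equal(unlist(perfect), c(acc = 1, sen = 1, spe = 1, mcc = 1, bacc = 1))

  # a published sensitivity/specificity pair: balanced accuracy is their mean
  sen <- 0.4881; spe <- 0.9742
  ms <- metric_set(list(tp = sen * 1e4, fn = (1 - sen) * 1e4,
                        tn = spe * 1e4, fp = (1 - spe) * 1e4))
  expect_equal(ms$bacc, 0.73115)
  expect_lte(abs(100 * ms$bacc - 73.12), 0.005 + 1e-9)  # printed-precision match

  sym <- metric_set(list(tp = 25, fp = 25, tn = 25, fn = 25))
  expect_equal(sym$acc, 0.5)
  expect_equal(sym$mcc, 0)

  # degenerate denominators
  expect_equal(metric_set(list(tp = 0, fp = 0, tn = 10, fn = 0))$mcc, 0)
  expect_true(is.nan(metric_set(list(tp = 0, fp = 0, tn = 10, fn = 0))$sen))
  expect_true(is.nan(metric_set(list(tp = 10, fp = 0, tn = 0, fn = 0))$spe))
  expect_error(metric_set(list(tp = 0, fp = 0, tn = 0, fn = 0)), "zero")
})

test_that("bacc is exactly (sen + spe) / 2 and mcc stays in [-1, 1]", {
  set.seed(97)
  for (i in 1:50) {
    cc <- list(tp = sample(0:30, 1), fp = sample(0:30, 1),
               tn = sample(0:30, 1), fn = sample(0:30, 1))
    if (sum(unlist(cc)) == 0) next
    ms <- metric_set(cc)
    if (is.finite(ms$bacc)) expect_equal(ms$bacc, (ms$sen + ms$spe) / 2)
    expect_gte(ms$mcc, -1); expect_lte(ms$mcc, 1)
  }
  expect_equal(metric_set(list(tp = 5, fp = 0, tn = 5, fn = 0))$mcc, 1)
  expect_equal(metric_set(list(tp = 0, fp = 5, tn = 0, fn = 5))$mcc, -1)
})

test_that("ROC points match per-threshold confusion recomputation", {
  y <- rep(c(0, 1), each = 10)
  perfect <- roc_curve(y, y)
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))
  expect_equal(auc(perfect), 1)

  const <- roc_curve(y, rep(0.7, 20))
  expect_equal(const$fpr, c(0, 1))
  expect_equal(const$tpr, c(0, 1))
  expect_equal(auc(const), 0.5)

  set.seed(101)
  s <- rnorm(20)
  r <- roc_curve(y, s)
  for (i in seq_len(nrow(r))) {
    pred <- as.integer(s > r$threshold[[i]])
    cc <- confusion(y, pred)
    expect_equal(r$fpr[[i]], cc$fp / (cc$fp + cc$tn))
    expect_equal(r$tpr[[i]], cc$tp / (cc$tp + cc$fn))
  }
  expect_equal(r$fpr[[1]], 0); expect_equal(r$tpr[[nrow(r)]], 1)
  expect_error(roc_curve(rep(1, 5), rnorm(5)), "both classes")
})

test_that("trapezoidal AUC equals rank-sum concordance; reversal flips it", {
  set.seed(103)
  for (i in 1:10) {
    y <- rbinom(60, 1, 0.5); if (length(unique(y)) < 2) y[1:2] <- 0:1
    s <- round(rnorm(60), 1)          # coarse scores force ties
    a <- auc(roc_curve(y, s))
    expect_equal(a, mw_auc(y, s), tolerance = 1e-12)
    expect_equal(auc(roc_curve(y, -s)), 1 - a, tolerance = 1e-12)
  }
})

test_that("undersampling balances the classes and only permutes balanced input", {
  # the 10x-scaled human-benchmark imbalance: 144 positives, 1594 negatives
  set.seed(107)
  X <- matrix(rnorm(1738 * 3), ncol = 3)
  ft <- sipfft:::new_features(X, ids = sprintf("u%04d", 1:1738),
                              labels = rep(c(1L, 0L), c(144, 1594)))
  bal <- undersample(ft, seed = 5)
  expect_identical(nrow(bal), 288L)
  expect_equal(sum(bal$label == 1), 144)
  expect_equal(sum(bal$label == 0), 144)
  expect_true(all(ft$id[ft$label == 1] %in% bal$id))  # minority kept whole

  balanced <- cluster_features(n_per = 10, p = 3, seed = 109)
  out <- undersample(balanced, seed = 6)
  expect_setequal(out$id, balanced$id)
  expect_identical(undersample(ft, seed = 5)$id, bal$id)  # seeded determinism

  ft1 <- sipfft:::new_features(X[1:10, ], ids = as.character(1:10),
                               labels = rep(1L, 10))
  expect_error(undersample(ft1), "both classes")
})

test_that("fold aggregation uses arithmetic means and sample SDs", {
  per_fold <- tibble::tibble(fold = 1:5, acc = c(0.8, 0.9, 0.7, 0.85, 0.95),
                             sen = c(0.5, NaN, 0.6, 0.4, 0.7))
  expect_warning(agg <- aggregate_folds(per_fold), "non-finite")
  expect_equal(agg$mean[agg$metric == "acc"], mean(per_fold$acc))
  expect_equal(agg$sd[agg$metric == "acc"], sd(per_fold$acc))
  expect_equal(agg$mean[agg$metric == "sen"], mean(c(0.5, 0.6, 0.4, 0.7)))
})

test_that("stratified folds partition the data with balanced prevalence", {
  set.seed(113)
  y <- rep(c(0L, 1L), c(60, 40))
  folds <- stratified_folds(y, 5)
  expect_setequal(unique(folds), 1:5)
  expect_equal(as.vector(table(folds)), rep(20, 5))
  for (f in 1:5) expect_equal(sum(y[folds == f] == 1), 8)
  expect_error(stratified_folds(rep(c(0, 1), c(3, 97)), 5), "at least")
})

test_that("cross-validation is reproducible, partitions ids, reports both arms", {
  ft <- cluster_features(n_per = 25, p = 6, delta = 4, seed = 127)
  cfg <- rp_config(B1 = 2L, B2 = 2L, q = 2L, k_grid = c(1L, 4L))
  cv <- kfold_cv(ft, models = c("rp", "svm"), rp = cfg, pca_q = 5L, seed = 21)

  expect_s3_class(cv, "sip_cv")
  expect_identical(sort(unique(cv$per_fold$model)), c("rp", "svm"))
  expect_identical(nrow(cv$per_fold), 10L)

  # test folds partition the sample ids (checked within one model arm)
  rp_pred <- dplyr::filter(cv$predictions, model == "rp")
  expect_setequal(rp_pred$id, ft$id)
  expect_identical(anyDuplicated(rp_pred$id), 0L)
  # both arms saw identical folds: paired comparison
  svm_pred <- dplyr::filter(cv$predictions, model == "svm")
  expect_identical(dplyr::select(rp_pred, fold, id), dplyr::select(svm_pred, fold, id))

  cv2 <- kfold_cv(ft, models = c("rp", "svm"), rp = cfg, pca_q = 5L, seed = 21)
  expect_equal(cv$per_fold, cv2$per_fold)

  gl <- glance(cv)
  expect_identical(nrow(gl), 2L)
  expect_true(all(c("acc_mean", "acc_sd", "auc_mean") %in% names(gl)))
  expect_equal(tidy(cv), cv$per_fold)

  md <- cv_markdown(cv)
  expect_length(grep("Average", md), 2L)

  path <- withr::local_tempfile(fileext = ".json")
  write_cv_json(cv, path)
  expect_true(jsonlite::validate(paste(readLines(path), collapse = "")))
})

test_that("autoplot returns ggplot objects for ROC and CV reports", {
  set.seed(131)
  y <- rep(c(0, 1), each = 15)
  r <- roc_curve(y, y + rnorm(30))
  expect_s3_class(autoplot(r), "ggplot")

  ft <- cluster_features(n_per = 15, p = 4, delta = 4, seed = 137)
  cv <- kfold_cv(ft, rp = rp_config(B1 = 1L, B2 = 1L, q = 2L, k_grid = c(1L, 4L)),
                 n_folds = 3, pca_q = 4L, seed = 7)
  expect_s3_class(autoplot(cv), "ggplot")
})
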