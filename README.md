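# sipfft

Sequence-based prediction of **self-interacting proteins (SIPs)** —
proteins whose copies, expressed from one gene, bind each other
(homo-oligomerisation). SIP detection cannot lean on the pairwise evidence
(co-expression, co-evolution) that ordinary protein–protein interaction
predictors use, and curated SIP benchmarks are heavily imbalanced
(e.g. 1441 positives vs 15,938 negatives in the human set). sipfft is an R
implementation of a spectral-profile pipeline for this setting:

1. **Profile.** Each protein is an `N x 20` position-specific scoring
   matrix `M` (PSSM), parsed from PSI-BLAST ASCII output
   (`parse_psiblast_pssm()`) or built from the bare sequence via the
   Dayhoff/PAM250 mutation matrix (`dayhoff_pssm()`,
   `M[a, b] = sum_k p(a, k) q(b, k)`).
2. **Descriptor.** The length-free Gram matrix `A = t(M) %*% M` (20 x 20)
   is transformed by a 2-D discrete Fourier transform with `1/N`
   normalisation per axis; the moduli of the 400 coefficients are the
   feature vector (`fft_features()`; DCT, SVD and column-covariance
   extractors are included for comparison). PCA reduces 400 to 300
   (`pca_fit()`, fit on training folds only by default).
3. **Classifier.** A random-projection ensemble (`rp_fit()`): `B1 = 10`
   KNN base learners, each trained on the best of `B2 = 30` random
   unit-column projections to dimension `q` (selected by leave-one-out
   error minimised over `k = 1, 4, ..., 40`), voting with a data-driven
   threshold `alpha` equal to the training prevalence of positives —
   `predict()` calls a SIP when the vote fraction exceeds `alpha`.
   An RBF-SVM baseline (`train_svm()`, LIBSVM with `c = 0.03`,
   `g = 1200`) runs on the same folds for paired comparison.
4. **Evaluation.** Stratified 5-fold cross-validation (`kfold_cv()`) with
   optional majority-class undersampling (`undersample()`), reporting
   Acc, Sen, Spe, MCC, balanced accuracy `(Sen + Spe)/2` and a true
   score-swept ROC/AUC, aggregated as mean ± sample SD across folds.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

No PSI-BLAST run is needed to try the pipeline: the package ships a seeded
synthetic-PSSM generator in which positives carry a periodic position
signal that the FFT descriptor is built to detect.

```r
library(sipfft)

ds <- generate_dataset(synthetic_spec(
  n_pos = 60, n_neg = 60, signal_amplitude = 0.5, seed = 42))
ft <- extract_features(ds$profiles, ds$labels, extractor = "FFT")
cv <- kfold_cv(ft, models = c("rp", "svm"), seed = 1)
cv
#> <sip_cv> 5-fold stratified cross-validation (seed 1)
#>   rp    ACC 71.67 +/- 6.85  SEN 58.33 +/- 13.18  SPE 85.00 +/- 16.03  MCC 46.37 +/- 14.35  BACC 71.67 +/- 6.85  AUC 0.8215
#>   svm   ACC 50.00 +/- 0.00  SEN  0.00 +/- 0.00  SPE 100.00 +/- 0.00  MCC  0.00 +/- 0.00  BACC 50.00 +/- 0.00  AUC 0.5000
```

At this weak signal-to-noise ratio (amplitude 0.5 against unit noise) the
projection ensemble recovers the positive class well above chance — 71.67%
accuracy, AUC 0.82 — while the SVM baseline at its published
hyperparameters predicts everything negative (sensitivity 0, the same
conservative behaviour it shows in the published benchmark tables bundled
as `benchmark_summary_metrics()`). Raising `signal_amplitude` to 2 drives
the ensemble to 100% on this benchmark. Per-fold detail and member-level
structure:

```r
tidy(cv)            # fold-by-fold Acc/Sen/Spe/MCC/B_Acc/AUC
glance(rp_fit(ft, seed = 1))
#> # A tibble: 1 x 7
#>      B1    B2     q law      n_train alpha mean_loo_error
#>   <int> <int> <int> <chr>      <int> <dbl>          <dbl>
#> 1    10    30     5 gaussian     120   0.5              0
autoplot(cv)        # per-fold ROC curves, one panel per model arm
```

Real profiles are produced outside R in the usual way, one file per
protein, then parsed with `parse_psiblast_pssm()`:

```sh
psiblast -query protein.fasta -db swissprot -num_iterations 3 \
         -evalue 0.001 -out_ascii_pssm protein.pssm
```

A shell interface for the main verbs is installed at `exec/sipfft`
(`sipfft simulate`, `sipfft extract`, `sipfft cv`).

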