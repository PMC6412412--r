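---
title: "Spectral PSSM features and random-projection ensembles for self-interacting protein prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral PSSM features and random-projection ensembles for self-interacting protein prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipfft)
```

## The problem

Self-interacting proteins (SIPs) are proteins whose copies, expressed from a
single gene, bind each other — homodimers and higher homo-oligomers. Because
a SIP "pair" is one protein twice, the pairwise features that drive ordinary
protein–protein interaction predictors (co-expression, co-localisation,
co-evolution of two partners) carry no signal, and curated SIP datasets are
strongly imbalanced: in the widely used human benchmark there are 1441
positives against 15,938 negatives, and 710 against 5511 in yeast. sipfft
implements a sequence-only pipeline for this setting: evolutionary profiles
summarised by a spectral descriptor, reduced by PCA, and classified by an
ensemble of k-nearest-neighbour (KNN) learners trained on random low-
dimensional projections, with an imbalance-aware voting threshold.

## From sequence to a fixed-length descriptor

**PSSM.** Each protein is represented by its position-specific scoring
matrix $M \in \mathbb{R}^{N\times 20}$, where $N$ is the sequence length and
$M_{\alpha\beta}$ scores residue $\beta$ at position $\alpha$. Profiles are
read from PSI-BLAST ASCII output (`parse_psiblast_pssm()`; the log-odds
block, not the percentage block, is retained — it is the block that scores
"finding this amino acid at this position"). When no profile is available,
`dayhoff_pssm()` builds a fallback: with a single sequence the per-position
frequency weights collapse to an indicator, so
$M_{\alpha\beta} = \sum_k p(\alpha,k)\,q(\beta,k)$ reduces to the
substitution-matrix row (Dayhoff-derived PAM250) of the residue at
$\alpha$. Unknown residues (`X`) get a zero row rather than an error;
benchmark assembly already filters pathological sequences. Column order is
taken from each file's header and re-ordered once, on ingest, into the
canonical alphabet `ACDEFGHIKLMNPQRSTVWY`, so Gram matrices from different
sources are comparable.

**Gram matrix.** Sequence lengths differ, so descriptors cannot come from
$M$ directly. The pipeline uses $A = M^\top M$, a $20\times20$ symmetric
positive semi-definite summary that is independent of $N$ and accumulates
the co-occurrence structure of the profile columns.

**Spectral descriptor.** The primary extractor applies the 2-D discrete
Fourier transform to $A$,
$$W_{uv} = \frac{1}{20}\cdot\frac{1}{20}\sum_{s=0}^{19}\sum_{t=0}^{19}
A_{st}\, e^{-2\pi i (us + vt)/20},$$
and keeps the modulus $|W_{uv}|$ of all 400 coefficients, flattened
row-major (`fft_features()`). Three choices here were genuinely open and are
worth recording:

* *Modulus, not real/imaginary parts.* The descriptor must have exactly 400
  real entries; the modulus (the power spectrum reading) achieves that,
  discards phase — which is dominated by arbitrary alignment of the profile
  — and is the standard spectrum summary. An interleaved real/imaginary
  encoding would also give 400 numbers but was rejected as non-standard.
* *Normalisation $1/N$ per axis*, so the DC coefficient equals the matrix
  mean and descriptor scale does not grow with matrix magnitude.
* *No standardisation of PSSM entries before the Gram product.* Raw
  log-odds are used; the Gram matrix is already a second-order summary.

Three comparison extractors share the surface: the orthonormal 2-D DCT-II
(`dct_features()`), the flattening of $U S$ from the SVD $A = USV^\top$
(`svd_features()`, a reconstruction choice — it is a baseline, not a claim),
and the $20\times20$ column covariance of the raw PSSM (`cov_features()`,
denominator $N-1$).

**PCA.** `pca_fit()` / `pca_transform()` (mean-centred, SVD-based) reduce
the 400 descriptors, conventionally to $q = 300$; `pca_q_capped()` caps $q$
at $\min(n_\text{train}-1, p)$ so small runs degrade gracefully. By default
PCA is fit on the training folds only and applied to the test fold — the
leakage-safe protocol. A `pca_global` flag reproduces the common (and
leakier) variant of fitting PCA once on the full dataset; on the synthetic
benchmark the two are indistinguishable, but the flag exists so both
protocols can be compared explicitly.

## The random-projection KNN ensemble

`rp_fit()` trains `B1 = 10` base learners. For each, `B2 = 30` candidate
projections $R \in \mathbb{R}^{q\times p}$ are drawn (i.i.d. Gaussian by
default, or Bernoulli $\pm1$; columns rescaled to unit $\ell_2$ norm) and
the training set is projected as $Z = XR^\top$. Each candidate is scored by
the leave-one-out (LOO) error of a KNN classifier on $Z$, minimised over the
neighbour grid $k \in \{1, 4, 7, \dots, 40\}$; the candidate with the
smallest error wins its block, so the $B1 \times B2$ draws form $B1$
non-overlapping selection blocks. At prediction time each member projects
the query with its stored $R$ and votes with its selected $k$ against its
stored projected training set; `vote_fraction()` is the proportion of
positive votes, and `predict()` calls a sample positive when that fraction
*strictly exceeds* $\alpha$, the training prevalence of positives. Taking
the class prior as the voting threshold is what lets the ensemble operate
on imbalanced data: with balanced (undersampled) training data
$\alpha = 0.5$ and voting is majority; at the raw human-benchmark
imbalance $\alpha = 1441/17379 \approx 0.083$ and a small minority of
positive votes already flags a SIP.

Parameters that matter, with defaults and reasoning:

* `q` (projected dimension, default **5**). No value is conventional for
  this pipeline; the random-projection ensemble literature consistently
  uses dimensions far below the ambient 300, and LOO-selected KNN
  overfits distance structure in high dimensions. It is the first knob a
  user should vary.
* `B1 = 10`, `B2 = 30`, `k_grid = seq(1, 40, 3)`: the standard operating
  point for this classifier family; all exposed in `rp_config()`.
* Tie-breaking is fully deterministic and documented: equidistant
  neighbours resolve to the lowest training index; an even-$k$ split vote
  resolves to class 1 iff the class-1 prior is at least 0.5; equal LOO
  errors resolve to the earliest-drawn candidate and then the smallest
  $k$. Runs are therefore bit-reproducible from (data, config, seed), and
  a `law = "identity"` hook (with $q = p$) collapses the whole machine to
  plain KNN for verification.

The SVM comparison arm (`train_svm()`) wraps LIBSVM via e1071 with the
benchmark hyperparameters `c = 0.03`, `g = 1200`, RBF kernel, no feature
scaling by default. Those values are unusual — a tiny penalty with an
enormous kernel width — and on unscaled spectral features they produce a
conservative classifier with near-zero sensitivity; that behaviour is
visible in the published comparison tables bundled with the package
(`benchmark_summary_metrics()`) and reproduces on the synthetic benchmark.
A `scale` flag is provided for experimentation.

## Evaluation protocol

`confusion()` and `metric_set()` implement accuracy, sensitivity,
specificity, MCC and balanced accuracy $(Sen+Spe)/2$. Degenerate cases are
defined, not fudged: MCC with a zero denominator is 0; a sensitivity or
specificity whose class is absent is `NaN` and is excluded from fold
averaging with a warning. `roc_curve()` sweeps every distinct score with
the strict convention *positive iff score > t* — the same inequality as the
vote threshold — and `auc()` integrates trapezoidally; the test suite pins
this to the Mann–Whitney concordance on random instances. The ensemble's
vote fraction is its ROC score (it is the model's only continuous output).
Note that published AUCs for this task sometimes numerically equal
B\_Acc/100, suggesting a single operating point rather than a swept curve;
sipfft computes the true swept AUC and reports balanced accuracy
separately.

`kfold_cv()` runs stratified 5-fold cross-validation (per-fold prevalence
within one sample of the global prevalence), fits PCA and the classifiers
per training split, and aggregates each metric as the arithmetic mean and
sample SD ($n-1$) across folds — the convention of the published benchmark
tables, which the acceptance tests verify cell-by-cell against
`benchmark_fold_metrics()`. Descriptions of this protocol sometimes
garble the fold count ("partitioned into 10 subsets ... remaining nine");
sipfft implements standard stratified $k$-fold with $k = 5$. When both
model arms are requested they share fold assignments, so comparisons are
paired. `undersample()` balances an imbalanced table by keeping the whole
minority class and an equal-size random subset of the majority class.

## The synthetic benchmark

Real profile datasets require PSI-BLAST runs against large sequence
databases, so the package validates itself on synthetic PSSMs
(`synthetic_spec()`, `generate_dataset()`). Negatives are i.i.d.
$\mathcal{N}(0, \sigma^2)$ matrices; positives add a sinusoid along the
sequence axis, $a\sin(2\pi\alpha/T)$, to a random 10 of the 20 columns.
Defaults: lengths uniform on 50–300 (the short end of the 50–5000 range
benchmark proteins are filtered to, keeping tests fast), period $T = 8$
positions (well inside any profile), noise $\sigma = 1$, amplitude
$a = 1$. The signal is *periodic in position* by design: it concentrates in
a few Fourier coefficients of the Gram matrix, giving the FFT extractor a
detectable target while leaving the DCT and covariance extractors partial
power — a qualitative, not quantitative, mirror of the published extractor
ordering. Amplitude 0 makes the classes exchangeable and is used as the
chance-level control.

What the generator does **not** emulate: the marginal distribution of real
log-odds scores, inter-column dependence induced by the substitution model,
alignment-depth effects on profile sharpness, or any biology of
self-interaction. Passing tests therefore demonstrate that the machinery is
correct and that the pipeline recovers the class structure it is designed
to detect — not that it attains any particular accuracy on real proteomes.

Problem sizes used in the validation suite, chosen to exercise the full
default configuration: the end-to-end recovery check uses $n = 200$
profiles (100 per class) at amplitude/noise ratio 5 across 5 seeds, where
5-fold CV accuracy is required to reach 0.90 and to beat the amplitude-0
control; behavioural checks (chance level under permuted labels,
monotonicity in amplitude, no loss from candidate selection) use $n = 80$
across 5–10 seeds; brute-force oracle comparisons run on 20×20 matrices and
instances of a few dozen points.

## Known limitations

* The projected dimension `q` and the exact voting rule at the threshold
  boundary are design decisions (documented above), not published
  constants; results can be sensitive to `q`.
* The SVM arm inherits its published hyperparameters as defaults; they are
  not re-tuned, and with unscaled features the arm is mainly useful as the
  conservative comparison it was in the original benchmark.
* `undersample()` discards majority-class information; alternatives
  (weighting, resampling ensembles) are out of scope.
* Storing each member's projected training set makes models grow linearly
  with $B1 \cdot n_\text{train} \cdot q$; for the dataset sizes this
  pipeline targets (thousands of proteins) that is acceptable.
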