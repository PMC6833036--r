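---
title: "Methods: raw-ECG stress classification with a dual-branch 1-D ConvNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: raw-ECG stress classification with a dual-branch 1-D ConvNet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Acute stress shifts autonomic balance: heart rate rises and beat-to-beat
(RR) variability falls. The classical route to detecting this from an ECG
is to locate R peaks, derive heart-rate-variability (HRV) parameters over
windows of at least several minutes, and feed those features to a
classifier. That pipeline needs long windows, clean R-peak detection and
manual feature selection. `stressecg` implements the alternative this
package is built around: a convolutional network that classifies **raw,
unfiltered ECG windows of 10-60 s** directly into rest vs. stress, with no
R-peak detection and no HRV features, plus the training and evaluation
protocol that makes such a classifier credible on small physiological
corpora.

Two acquisition protocols are modeled. An *ambulatory driving* protocol
records ECG at 496 Hz with 15-min rests flanking a long drive (city and
highway driving are labeled stress). A *laboratory mental-arithmetic*
protocol records at 256 Hz and alternates 5-min rest and 5-min task blocks
twice, so each subject contributes 600 s of rest and 600 s of stress.

## Preprocessing

1. **Per-stressor z-scoring.** All samples of one stressor's records are
   pooled; their mean and *population* standard deviation (divisor `n`)
   standardize every record of that stressor. The population/sample
   distinction is negligible at millions of samples. The original protocol
   pools every subject, which leaks test-set statistics into training; the
   cross-validation driver therefore fits the statistics on training-fold
   subjects only and reuses them on the test fold, while `paper_exact =
   TRUE` reproduces the pooled variant. With millions of pooled samples
   per fold the two differ only marginally - the option exists for
   fidelity, the default for hygiene.
2. **Resampling.** Driving records are downsampled 496 -> 256 Hz by
   rational polyphase filtering (ratio 16/31; windowed-sinc FIR, Hamming
   window, 10 lobes per side). Any anti-aliased method would do; the test
   suite pins behavior with a zero-crossing-preservation oracle on a
   band-limited tone. Normalization is applied after downsampling (the
   order is unstated in the source protocol; since both operations are
   linear the choice only affects edge transients).
3. **Windowing.** Each labeled segment is cut into
   `floor(duration / window_s)` consecutive non-overlapping windows
   anchored at the segment start; the remainder is dropped and windows
   never cross segment boundaries (labels would be ambiguous). This rule
   uniquely reproduces the published mental-arithmetic sample counts
   (17 subjects x 600 s per class: 1020/1020 at 10 s, 340/340 at 30 s,
   170/170 at 60 s). City, highway and task segments map to stress; rest
   to rest. Class imbalance in the driving corpus is left as-is.

## The network

The input is a batch `[m, w, 1]` with `w = 256 * window_s`. Eight stages
are stacked; stage `N`:

* convolution, width 16, stride 1, same padding, `c(N)/2` filters;
* two parallel subsampling branches on that output: a width-16
  **strided convolution** (stride 2, `c(N)/2` filters) and a width-16
  **max-pooling** (stride 2);
* channel concatenation of the branches, batch normalization (trainable
  gamma/beta), ReLU, dropout 0.3.

Width halves exactly at each stage (same padding is forced by the
closed-form dimension contract), so the stage-`N` feature map is
`[m, w / 2^N, c(N)]` with the channel schedule
`c(N) = 8 * 2^floor((N-1)/2)` = 8, 8, 16, 16, 32, 32, 64, 64. The
stage-8 features are flattened into one linear layer producing two logits
and a softmax; rows of the output sum to 1.

**Channel bookkeeping.** The source's per-layer table lists `8 * 2^k`
filters per convolutional layer while its dimension equations require the
*concatenated* stage output to have `8 * 2^k` channels (each branch
carrying half). The equations are the only internally consistent,
testable statement, so they are the default (`channel_mode =
"equations"`); `channel_mode = "table3"` builds the literal-table variant
(stage outputs 16..128) for comparison. The probe-batch shape tests are
the normative contract.

Other numerical choices that the source leaves open: batch-norm epsilon
1e-5 and running-statistics momentum 0.99 (running estimates therefore
need on the order of a hundred mini-batches to converge - on small
synthetic cohorts early-epoch test accuracy is unstable until they catch
up, which the best-epoch selection rule absorbs); max-pooling ties broken
by the first maximum (value-irrelevant); the head is a single linear
layer on flattened stage-8 features.

## Training

Binary cross-entropy `L = -(1/m) * sum(y log h + (1-y) log(1-h))` with
probabilities clipped at 1e-12 (guard against `log(0)`; not part of the
source formulation), mini-batches of 64, Adam (beta1 0.9, beta2 0.999,
eps 1e-8), He initialization `W ~ N(0, 2/n_in)` with fan-in
`filter_width * in_channels`, at most 10 epochs, and step decay of the
learning rate by 10 every 5 epochs. One epoch is a full pass over
shuffled windows (seeded). The source's transfer-learning update formula
omits the square root on the second moment; this is read as a typo and
standard Adam (`sqrt(v_hat) + eps`) is implemented.

Three regimes:

* **I** - from scratch on the driving corpus, base lr 1e-3 (the
  pretraining corpus is larger);
* **II** - from scratch on the mental-arithmetic corpus, same
  hyperparameters;
* **III** - transfer: stages 1-8 copied from a regime-I checkpoint, the
  softmax head re-initialized (He), stages 1-7 frozen, base lr 1e-4.

Freezing is bit-exact and includes batch-norm gamma/beta *and running
statistics*; frozen stages run in inference mode during training (no
dropout, running statistics). Because that makes the frozen prefix
deterministic, stage-7 features are computed once per dataset and only
stage 8 plus the head are iterated - a large speedup that guarantees the
freezing contract by construction. Adam moments for regime III start
fresh. Model selection keeps the epoch snapshot with the highest test-set
accuracy (the source's own - leaky - rule); passing a held-out validation
set instead is the caller's choice, and without a test set the training
accuracy is used.

## Evaluation

Subject-wise k-fold cross-validation (k = 10): whole subjects are
randomly dealt to folds (sizes differing by at most one), so no subject's
windows appear in both splits - with 17 subjects and k = 10, folds hold
one or two subjects. Metrics: accuracy, sensitivity (recall on stress),
specificity, precision, F1 (harmonic mean - the source's phrase "mean of
sensitivity and precision" is read as the standard F1 it names), and
trapezoidal ROC AUC over all distinct score thresholds. The decision rule
is argmax, i.e. stress when `P(stress) > 0.5`. The AUC implementation is
pinned to the normalized Mann-Whitney U statistic by a property test;
PR-curve points are pinned to an exhaustive threshold sweep. Regime
comparisons use one-way ANOVA plus Tukey's HSD at the 0.05 and 0.001
levels. Per-fold ROC/PR curves and a pooled-score curve are both emitted,
since the source does not state how curves were averaged across folds.

Conventional baselines (decision tree, kNN, logistic regression, random
forest, linear SVM) run on raw windows as flat standardized vectors under
the same fold plan. kNN and logistic regression use FNN and glmnet; no
CART/SVM/random-forest package exists in the supported environment, so
compact implementations live in the package (a gini tree with quantile
candidate splits, bagging with `sqrt(p)` feature sampling, full-batch
squared-hinge descent). Their published role - and what the tests assert -
is that they sit at chance on raw ECG; exact accuracies of any particular
mainstream implementation are not reproduced.

## The synthetic cohort generator

No generative model is published, so the simulator is the package's own
stated world, chosen once:

* RR intervals are Gaussian around `60 / mean_hr` with a sinusoidal
  respiratory modulation at 0.25 Hz carrying 30% of the RR variance
  (respiratory sinus arrhythmia) and a physiologic floor at a quarter of
  the mean interval; `sdnn_ms = 0` degenerates to an exactly periodic
  train.
* Each beat is a sum-of-Gaussians P-QRS-T template placed at the midpoint
  of its RR interval, plus white sensor noise (default SD 0.05 mV against
  a 1 mV R wave - a mildly noisy single-lead recording).
* Condition defaults: rest 65 bpm / SDNN 50 ms, stress 85 bpm / SDNN
  25 ms - a textbook-sized autonomic response, and package defaults
  rather than published values. Per-subject uniform +/-10% jitter on rate
  and SDNN (from the subject seed) makes subjects distinct without
  destroying separability.
* Protocols: the mental-arithmetic session is rest/stress/rest/stress at
  300 s each, 256 Hz; the driving session is 15 min rest, a 45-min
  driving block (configurable; real sessions ranged 50-85 min total)
  split into city and highway halves, then 15 min rest, 496 Hz. The
  city/highway alternation of the real protocol is not recoverable from
  the text, so driving is one contiguous stress block.
* Everything is seeded: per-subject and per-segment seeds derive
  deterministically from the cohort seed, so identical inputs give
  bit-identical cohorts.

What the simulator does *not* emulate: morphology change under stress,
ectopy and artifacts, electrode noise spectra, baseline wander,
inter-lead differences. A green end-to-end test therefore establishes
that the pipeline can learn a rate/variability contrast through raw
waveforms - the mechanism the architecture is built to exploit - not that
it reaches any particular accuracy on real recordings, which require the
real corpora and are out of scope here.

The generator guarantees the learning problem is solvable (a bare
mean-heart-rate threshold on 60-s windows separates the default
conditions essentially perfectly - itself a tested property), so a
network that fails to learn indicates an implementation defect, not an
impossible task. The end-to-end learning tests use scaled-down cohorts
(10 mental-arithmetic subjects held out two; 4 driving subjects with a
30-min stress block for pretraining) to keep the suite inside its
runtime budget; the sizes were chosen once for budget, and the tests
compute every number they assert - from-scratch training must reach
held-out accuracy at least 0.90 within the 10-epoch cap, and
transfer-learning accuracy averaged over five seeds must match or exceed
it.

## Known limitations

* No GPU path and no recurrent/attention variants; the architecture is
  exactly the eight-stage dual-branch design.
* The WFDB layer reads/writes single-channel format-16 records with a
  delimited-text marker sidecar; it is not a general WFDB implementation.
* The in-package tree/forest/SVM baselines are deliberately simple
  stand-ins for mainstream implementations.
* Hardware-timing claims (milliseconds-per-inference) are out of scope.
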