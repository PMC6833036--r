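# stressecg

Binary **stress detection from raw, unfiltered ECG** with an eight-stage
dual-branch 1-D convolutional network — no R-peak detection, no
heart-rate-variability features, windows as short as 10 s.

Acute stress raises heart rate and suppresses beat-to-beat variability.
Classical detectors extract HRV parameters from minutes of clean ECG;
this package instead trains an end-to-end classifier on z-scored raw
windows. Each network stage applies a width-16 convolution and
downsamples it through two parallel branches — a stride-2 convolution
and a stride-2 max-pooling — concatenated along channels, followed by
batch normalization, ReLU and dropout (0.3). For a window of
`w = 256 × window_s` samples, stage `N` yields a feature map

```
sigma(N) ∈ R^[m × w/2^N × c(N)],   c(N) = 8·2^floor((N−1)/2) = 8,8,16,16,32,32,64,64
```

and a softmax head on the flattened stage-8 features returns
`P(rest), P(stress)`. Training uses binary cross-entropy, Adam
(β₁ = 0.9, β₂ = 0.999, ε = 1e−8), He initialization, batches of 64, at
most 10 epochs, and a step-decayed learning rate (×0.1 every 5 epochs).
Three regimes mirror the published protocol: **I** — from scratch on an
ambulatory driving corpus (496 Hz, resampled to 256 Hz); **II** — from
scratch on a laboratory mental-arithmetic corpus (256 Hz); **III** —
transfer learning from a regime-I checkpoint with stages 1–7 frozen
bit-exactly (including batch-norm statistics), the softmax head
re-initialized, and base learning rate 1e−4. Evaluation is subject-wise
10-fold cross-validation with accuracy, sensitivity, specificity, F1,
ROC/PR curves and ANOVA + Tukey regime comparison, plus conventional
baselines (tree, kNN, logistic regression, random forest, linear SVM)
on raw windows.

Because the real corpora are not distributable, the package includes a
seeded **synthetic cohort simulator** (Gaussian-template P-QRS-T beats on
a respiration-modulated RR process; rest 65 bpm / SDNN 50 ms vs. stress
85 bpm / SDNN 25 ms by default) that emulates both acquisition protocols,
so the entire pipeline is buildable and testable offline. The network,
backpropagation, Adam and the resampler are implemented in the package
itself (R + Rcpp/RcppArmadillo kernels); no deep-learning framework is
required.

## Worked example

```r
library(stressecg)

# a 10-subject laboratory cohort: 5-min rest/task alternation at 256 Hz;
# normalization statistics fitted on the 8 training subjects only
cohort <- simulate_cohort(ma_protocol(), n_subjects = 10, cohort_seed = 11)
ids    <- vapply(cohort$records, function(r) r$subject_id, "")
stats  <- fit_norm_stats(cohort$records[!(ids %in% c("MA09", "MA10"))])
recs   <- lapply(cohort$records, apply_norm, stats = stats)
ds     <- slice_windows(recs, window_s = 10)
print(ds)
#> <windowed_dataset> 1200 windows [n, 2560, 1] (10 s @ 256 Hz),
#>   600 rest / 600 stress, 10 subjects (mental_arithmetic)

label_distribution(ds)     # floor(300 s / 10 s) x 4 segments x 10 subjects
#>   n_rest n_stress  n_total
#>      600      600     1200

cfg <- model_config(window_s = 10)
stage_output_shape(cfg, 8)       # stage-8 features: w / 2^8 = window_s
#>    width channels
#>       10       64

sp  <- split_by_subject(ds, c("MA09", "MA10"))   # held-out subjects
fit <- train(build_model(cfg, seed = 1), sp$train,
             train_config("II", max_epochs = 10, seed = 5),
             test_ds = sp$test)                  # ~3 min on one CPU
tail(fit$log, 2)
#>  epoch    lr       loss train_acc  test_acc
#>      8 1e-04 0.07276072 0.9781250 0.9958333
#>      9 1e-04 0.06398581 0.9791667 0.9958333
fit$best_epoch
#> [1] 8

m <- compute_metrics(predict(fit$net, sp$test)$prob[, "stress"], sp$test$y)
print(m)
#> <stress_metrics> acc 0.996 | auc 1.000 | f1 0.996 | sens 1.000 |
#>   spec 0.992  (TP 120 FP 1 TN 119 FN 0)
```

The held-out subjects' windows are classified at 99.6% accuracy: the
network has learned the rate/variability contrast between the simulated
rest and stress states from raw waveforms. Under the same protocol,
transfer learning (regime III, pretrained on a larger synthetic driving
cohort, stages 1-7 frozen) reaches 100% on every seed probed by the
acceptance suite.

The numbers printed by `label_distribution()` are the windowing
arithmetic the pipeline is pinned to: a 17-subject cohort yields exactly
2040 / 680 / 340 windows at 10 / 30 / 60 s with 1020/1020 and 170/170
class splits at 10 s and 60 s.

Command-line pipeline (same steps as above, with manifests):

```sh
CLI=$(Rscript -e 'cat(system.file("cli.R", package = "stressecg"))')
Rscript $CLI simulate   --protocol ma --subjects 4 --seed 7 --out records/
Rscript $CLI preprocess --in records/ --window 10 --out ds.rds
Rscript $CLI train      --data ds.rds --regime II --test-subjects MA04 --out net.rds
Rscript $CLI evaluate   --records records/ --window 10 --regime II --k 4 --report report/
```

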