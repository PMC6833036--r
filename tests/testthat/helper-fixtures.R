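# Shared fixtures, built in code at test time.

# tiny mental-arithmetic cohort, normalized and sliced
make_ma_dataset <- function(n_subjects = 2, window_s = 10, cohort_seed = 42) {
  coh <- simulate_cohort(ma_protocol(), n_subjects, cohort_seed = cohort_seed)
  stats <- fit_norm_stats(coh$records)
  recs <- lapply(coh$records, apply_norm, stats = stats)
  slice_windows(recs, window_s)
}

# linearly separable toy windows: two constant-offset classes
make_toy_dataset <- function(n = 128, w = 2560, offset = 1, seed = 1,
                             n_subjects = 4) {
  with_seed(seed, {
    X <- matrix(rnorm(w * n, 0, 0.3), w, n)
    y <- rep(c(0L, 1L), length.out = n)
    X[, y == 1] <- X[, y == 1] + offset
    structure(list(x = X, y = y,
                   subject_id = rep(sprintf("T%02d", seq_len(n_subjects)),
                                    length.out = n),
                   window_s = w / 256, fs = 256, stressor = "toy"),
              class = "windowed_dataset")
  })
}

# one record with prescribed segment durations (seconds)
make_segment_record <- function(durations, conditions, fs = 256,
                                subject_id = "S1", seed = 3) {
  n <- round(sum(durations) * fs)
  samples <- with_seed(seed, rnorm(n))
  ends <- cumsum(durations)
  ecg_record(subject_id, samples, fs,
             data.frame(condition = conditions,
                        start_s = c(0, ends[-length(ends)]), end_s = ends),
             stressor = "mental_arithmetic")
}

zero_crossings <- function(x) sum(diff(sign(x)) != 0)
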