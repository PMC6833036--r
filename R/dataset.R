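#' Slice labeled records into fixed-width training windows
#'
#' Cuts each marked segment into consecutive non-overlapping windows of
#' `window_s` seconds anchored at the segment start; remainder samples are
#' dropped and no window crosses a segment boundary. Windows inherit the
#' binary label of their segment (`stress_*` -> 1, `rest` -> 0). Records
#' must already be at 256 Hz (see [resample_record()]) and normalized.
#'
#' @param records list of [ecg_record()]s (or a `synthetic_cohort`).
#' @param window_s window length in seconds: 10, 30 or 60.
#' @return object of class `windowed_dataset`: list with `x` (matrix
#'   `w x n` of samples, `w = 256 * window_s`), `y` (integer 0/1 labels),
#'   `subject_id` (character per window), `window_s`, `fs`, `stressor`.
#' @export
#' @examples
#' coh <- simulate_cohort(ma_protocol(), 2, cohort_seed = 3)
#' ds <- slice_windows(coh$records, 10)
#' label_distribution(ds)
slice_windows <- function(records, window_s) {
  if (inherits(records, "synthetic_cohort")) records <- records$records
  if (inherits(records, "ecg_record")) records <- list(records)
  if (!window_s %in% c(10, 30, 60))
    abort("window_s must be one of 10, 30, 60, got %s", format(window_s))
  fs <- 256
  w <- as.integer(window_s * fs)
  xs <- list()
  ys <- integer(0)
  sids <- character(0)
  stressors <- character(0)
  for (rec in records) {
    if (!inherits(rec, "ecg_record")) abort("records must be ecg_record objects")
    if (rec$fs != fs)
      abort("record '%s' is at %g Hz; resample to %g Hz first",
            rec$subject_id, rec$fs, fs)
    stressors <- union(stressors, rec$stressor)
    for (g in seq_len(nrow(rec$markers))) {
      dur <- rec$markers$end_s[g] - rec$markers$start_s[g]
      n_win <- floor(dur / window_s)
      if (n_win < 1) next
      s0 <- round(rec$markers$start_s[g] * fs)
      lab <- condition_label(rec$markers$condition[g])
      for (j in seq_len(n_win)) {
        idx <- s0 + (j - 1L) * w + seq_len(w)   # half-open [start, start + w)
        xs[[length(xs) + 1L]] <- rec$samples[idx]
        ys <- c(ys, lab)
        sids <- c(sids, rec$subject_id)
      }
    }
  }
  x <- if (length(xs)) matrix(unlist(xs, use.names = FALSE), nrow = w)
       else matrix(numeric(0), nrow = w, ncol = 0)
  structure(list(x = x, y = ys, subject_id = sids,
                 window_s = window_s, fs = fs,
                 stressor = paste(sort(stressors), collapse = "+")),
            class = "windowed_dataset")
}

#' Label distribution of a windowed dataset
#'
#' @param ds a `windowed_dataset`.
#' @return named integer vector `c(n_rest, n_stress, n_total)`.
#' @export
label_distribution <- function(ds) {
  if (!inherits(ds, "windowed_dataset")) abort("ds must be a windowed_dataset")
  n_stress <- sum(ds$y == 1L)
  n_rest <- sum(ds$y == 0L)
  c(n_rest = n_rest, n_stress = n_stress, n_total = n_rest + n_stress)
}

#' @export
print.windowed_dataset <- function(x, ...) {
  d <- label_distribution(x)
  cat(sprintf(paste0("<windowed_dataset> %d windows [n, %d, 1] (%g s @ %g Hz), ",
                     "%d rest / %d stress, %d subjects (%s)\n"),
              d["n_total"], nrow(x$x), x$window_s, x$fs,
              d["n_rest"], d["n_stress"], length(unique(x$subject_id)),
              x$stressor))
  invisible(x)
}

# subset windows by logical/integer index (internal)
ds_subset <- function(ds, idx) {
  structure(list(x = ds$x[, idx, drop = FALSE], y = ds$y[idx],
                 subject_id = ds$subject_id[idx], window_s = ds$window_s,
                 fs = ds$fs, stressor = ds$stressor),
            class = "windowed_dataset")
}

#' Split a windowed dataset by subject
#'
#' @param ds a `windowed_dataset`.
#' @param test_subjects character vector of held-out subject IDs.
#' @return list with `train` and `test` windowed datasets.
#' @export
split_by_subject <- function(ds, test_subjects) {
  te <- ds$subject_id %in% test_subjects
  if (!any(te)) abort("no windows match the given test subjects")
  list(train = ds_subset(ds, !te), test = ds_subset(ds, te))
}
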