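CONDITIONS <- c("rest", "stress_city", "stress_highway", "stress_task")

#' A continuous, labeled single-channel ECG recording
#'
#' One subject's ECG with its sampling rate, stressor, and segment markers.
#' Marker conditions are `rest`, `stress_city`, `stress_highway` or
#' `stress_task`; all three stress variants map to the `stress` class.
#'
#' @param subject_id character scalar.
#' @param samples numeric vector, mV; must be finite.
#' @param fs sampling rate, Hz (`> 0`).
#' @param markers data.frame with `condition`, `start_s`, `end_s`;
#'   non-overlapping and within `[0, length(samples) / fs]`.
#' @param stressor `"driving"` or `"mental_arithmetic"`.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(subject_id, samples, fs, markers,
                       stressor = c("mental_arithmetic", "driving")) {
  stressor <- match.arg(stressor)
  if (!is.character(subject_id) || length(subject_id) != 1L)
    abort("subject_id must be a character scalar")
  stopifnot_scalar_num(fs, "fs")
  if (fs <= 0) abort("fs must be > 0")
  if (!is.numeric(samples)) abort("samples must be numeric")
  if (anyNA(samples) || any(!is.finite(samples)))
    abort("record '%s': samples must be finite", subject_id)
  if (!is.data.frame(markers) ||
      !all(c("condition", "start_s", "end_s") %in% names(markers)))
    abort("markers must have columns condition, start_s, end_s")
  if (!all(markers$condition %in% CONDITIONS))
    abort("record '%s': unknown marker condition(s): %s", subject_id,
          paste(setdiff(markers$condition, CONDITIONS), collapse = ", "))
  o <- order(markers$start_s)
  markers <- markers[o, , drop = FALSE]
  rownames(markers) <- NULL
  dur <- length(samples) / fs
  if (any(markers$end_s <= markers$start_s))
    abort("record '%s': markers must satisfy end_s > start_s", subject_id)
  if (min(markers$start_s) < -1e-9 || max(markers$end_s) > dur + 1e-6)
    abort("record '%s': markers outside [0, %g] s", subject_id, dur)
  if (nrow(markers) > 1 &&
      any(markers$start_s[-1] < markers$end_s[-nrow(markers)] - 1e-9))
    abort("record '%s': overlapping markers", subject_id)
  structure(list(subject_id = subject_id, samples = as.numeric(samples),
                 fs = fs, markers = markers, stressor = stressor),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s (%s): %d samples @ %g Hz (%.1f s), %d markers\n",
              x$subject_id, x$stressor, length(x$samples), x$fs,
              length(x$samples) / x$fs, nrow(x$markers)))
  invisible(x)
}

#' Map a marker condition to the binary class label
#'
#' @param condition character vector of marker conditions.
#' @return integer vector: 0 = rest, 1 = stress.
#' @export
condition_label <- function(condition) {
  if (!all(condition %in% CONDITIONS))
    abort("unknown condition(s): %s",
          paste(setdiff(condition, CONDITIONS), collapse = ", "))
  as.integer(condition != "rest")
}

marker_path <- function(path) paste0(path, ".markers.csv")

#' Write an ECG record to disk
#'
#' Two on-disk layouts share a delimited-text marker sidecar
#' (`<path>.markers.csv` with `condition,start_s,end_s`):
#' \describe{
#'   \item{`text`}{`<path>.ecg.txt`, one sample (mV) per line, plus a
#'     `<path>.meta.json` header with subject, fs and stressor.}
#'   \item{`wfdb`}{a waveform-database style pair `<path>.hea` /
#'     `<path>.dat` (format 16, little-endian 16-bit, gain 200 adu/mV,
#'     signal name ECG).}
#' }
#'
#' @param record an [ecg_record()].
#' @param path file path prefix (no extension).
#' @param format `"text"` or `"wfdb"`.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = c("text", "wfdb")) {
  format <- match.arg(format)
  if (!inherits(record, "ecg_record")) abort("record must be an ecg_record")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(record$markers, marker_path(path), row.names = FALSE)
  if (format == "text") {
    writeLines(formatC(record$samples, format = "g", digits = 9),
               paste0(path, ".ecg.txt"))
    jsonlite::write_json(
      list(subject_id = record$subject_id, fs = record$fs,
           stressor = record$stressor, units = "mV"),
      paste0(path, ".meta.json"), auto_unbox = TRUE)
  } else {
    gain <- 200
    adc <- as.integer(pmin(32767, pmax(-32768, round(record$samples * gain))))
    rec_name <- basename(path)
    chk <- sum(adc) %% 65536
    if (chk >= 32768) chk <- chk - 65536
    writeLines(c(
      sprintf("%s 1 %g %d", rec_name, record$fs, length(adc)),
      sprintf("%s.dat 16 %d(0)/mV 16 0 %d %d 0 ECG", rec_name, gain,
              adc[1] %||% 0, chk),
      sprintf("# stressor: %s", record$stressor),
      sprintf("# subject_id: %s", record$subject_id)),
      paste0(path, ".hea"))
    con <- file(paste0(path, ".dat"), "wb")
    on.exit(close(con))
    writeBin(adc, con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_markers <- function(path, record_name) {
  mf <- marker_path(path)
  if (!file.exists(mf))
    abort("record '%s' excluded: no marker sidecar found at '%s'",
          record_name, mf, class = "stressecg_load_error")
  read.csv(mf, stringsAsFactors = FALSE)
}

#' Read an ECG record from disk
#'
#' Loads a record written by [write_record()] (or any conforming layout).
#' Records without a marker sidecar are rejected with a load error naming
#' the record, mirroring the exclusion of unmarked subjects from analysis.
#'
#' @param path file path prefix (no extension).
#' @param format `"text"` or `"wfdb"`.
#' @return an [ecg_record()].
#' @export
read_record <- function(path, format = c("text", "wfdb")) {
  format <- match.arg(format)
  rec_name <- basename(path)
  markers <- read_markers(path, rec_name)
  if (format == "text") {
    sf <- paste0(path, ".ecg.txt")
    mf <- paste0(path, ".meta.json")
    if (!file.exists(sf))
      abort("record '%s': signal file '%s' not found", rec_name, sf,
            class = "stressecg_load_error")
    if (!file.exists(mf))
      abort("record '%s': metadata file '%s' not found", rec_name, mf,
            class = "stressecg_load_error")
    meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
    samples <- as.numeric(readLines(sf))
    ecg_record(meta$subject_id, samples, meta$fs, markers, meta$stressor)
  } else {
    hf <- paste0(path, ".hea")
    if (!file.exists(hf))
      abort("record '%s': header '%s' not found", rec_name, hf,
            class = "stressecg_load_error")
    lines <- readLines(hf)
    hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    n_sig <- as.integer(hdr[2])
    fs <- as.numeric(hdr[3])
    n <- as.integer(hdr[4])
    sig_lines <- lines[seq(2, length.out = n_sig)]
    sig_names <- vapply(strsplit(trimws(sig_lines), "\\s+"),
                        function(f) f[length(f)], "")
    which_ecg <- match("ECG", sig_names)
    if (is.na(which_ecg))
      abort("record '%s': no ECG channel in header", rec_name,
            class = "stressecg_load_error")
    fields <- strsplit(trimws(sig_lines[which_ecg]), "\\s+")[[1]]
    if (fields[2] != "16")
      abort("record '%s': only format 16 supported", rec_name,
            class = "stressecg_load_error")
    gain <- as.numeric(sub("\\(.*$", "", fields[3]))
    con <- file(paste0(path, ".dat"), "rb")
    on.exit(close(con))
    adc <- readBin(con, "integer", n = n * n_sig, size = 2L, signed = TRUE,
                   endian = "little")
    if (n_sig > 1) adc <- adc[seq(which_ecg, length(adc), by = n_sig)]
    stressor <- sub("^# stressor: ", "",
                    grep("^# stressor: ", lines, value = TRUE)[1])
    sid <- sub("^# subject_id: ", "",
               grep("^# subject_id: ", lines, value = TRUE)[1])
    if (is.na(sid)) sid <- rec_name
    if (is.na(stressor)) stressor <- "mental_arithmetic"
    ecg_record(sid, adc / gain, fs, markers, stressor)
  }
}

# Windowed-sinc low-pass for polyphase resampling by L/M: cutoff at the
# tighter Nyquist edge, Hamming window, gain L.
design_lowpass <- function(L, M, lobes = 10) {
  f <- max(L, M)
  half <- lobes * f
  n <- 2L * half + 1L
  i <- seq_len(n) - 1L - half
  fc <- 1 / (2 * f)
  h <- 2 * fc * ifelse(i == 0, 1, sin(2 * pi * fc * i) / (2 * pi * fc * i))
  w <- 0.54 + 0.46 * cos(pi * i / half)
  h <- h * w
  h * L / sum(h)   # unity DC gain after upsampling by L
}

#' Resample a record to a target sampling rate
#'
#' Rational polyphase resampling (anti-aliased windowed-sinc FIR). For the
#' driving corpus this downsamples 496 Hz to the common 256 Hz rate
#' (reduced ratio 16/31). Markers are expressed in seconds and unchanged.
#'
#' @param record an [ecg_record()].
#' @param target_fs target sampling rate, Hz; default 256.
#' @return an [ecg_record()] with `round(n * target_fs / fs)` samples. If
#'   `fs` already equals `target_fs`, the record is returned unchanged.
#' @export
resample_record <- function(record, target_fs = 256) {
  if (!inherits(record, "ecg_record")) abort("record must be an ecg_record")
  stopifnot_scalar_num(target_fs, "target_fs")
  if (target_fs <= 0) abort("target_fs must be > 0")
  if (record$fs == target_fs) return(record)
  r1 <- as.integer(round(target_fs))
  r0 <- as.integer(round(record$fs))
  if (abs(target_fs - r1) > 1e-9 || abs(record$fs - r0) > 1e-9)
    abort("resampling requires integer sampling rates")
  g <- gcd_int(r1, r0)
  L <- r1 %/% g
  M <- r0 %/% g
  h <- design_lowpass(L, M)
  y <- cpp_resample_poly(record$samples, L, M, h)
  rec <- record
  rec$samples <- as.numeric(y)
  rec$fs <- target_fs
  rec
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Per-stressor normalization statistics
#'
#' `fit_norm_stats()` pools all samples of one stressor's records and
#' returns the mean and population standard deviation; `apply_norm()`
#' z-scores a record with those statistics. Fitting on training-fold
#' subjects only and reusing the statistics on the test fold avoids
#' train/test leakage; pooling everything reproduces the original
#' protocol (see `paper_exact` options downstream).
#'
#' @param records list of [ecg_record()]s from a single stressor.
#' @return `fit_norm_stats`: object of class `norm_stats` with fields
#'   `mu`, `sigma`, `stressor`, `n`.
#' @export
fit_norm_stats <- function(records) {
  if (inherits(records, "ecg_record")) records <- list(records)
  if (length(records) == 0) abort("no records supplied")
  stressors <- unique(vapply(records, function(r) r$stressor, ""))
  if (length(stressors) != 1)
    abort("all records must share one stressor, got: %s",
          paste(stressors, collapse = ", "))
  n <- sum(vapply(records, function(r) length(r$samples), 0))
  if (n < 2) abort("need at least 2 pooled samples")
  total <- sum(vapply(records, function(r) sum(r$samples), 0))
  mu <- total / n
  ss <- sum(vapply(records, function(r) sum((r$samples - mu)^2), 0))
  sigma <- sqrt(ss / n)   # population SD
  if (sigma <= 0) abort("pooled SD is zero (constant signal)")
  structure(list(mu = mu, sigma = sigma, stressor = stressors, n = n),
            class = "norm_stats")
}

#' @rdname fit_norm_stats
#' @param record an [ecg_record()].
#' @param stats a `norm_stats` object.
#' @return `apply_norm`: the z-scored [ecg_record()].
#' @export
apply_norm <- function(record, stats) {
  if (!inherits(record, "ecg_record")) abort("record must be an ecg_record")
  if (!inherits(stats, "norm_stats")) abort("stats must be norm_stats")
  record$samples <- (record$samples - stats$mu) / stats$sigma
  record$normalized <- TRUE
  record
}
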