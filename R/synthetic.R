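#' Beat-generation parameters for the synthetic ECG simulator
#'
#' Describes one condition (rest or stress) as a mean heart rate, an RR
#' variability (SDNN), a respiratory modulation frequency, a beat amplitude
#' and an additive white-noise level. The rest/stress contrast these
#' parameters encode is the physiologic signal the classifier must learn:
#' acute stress raises heart rate and suppresses RR variability.
#'
#' @param mean_hr mean heart rate, beats/min; must lie in `[30, 220]`.
#' @param sdnn_ms standard deviation of RR intervals, ms; `>= 0`.
#' @param respiratory_mod_hz frequency of the sinusoidal respiratory
#'   modulation of RR intervals (respiratory sinus arrhythmia), Hz.
#' @param amplitude_mv R-wave amplitude, mV; `> 0`.
#' @param noise_sd_mv standard deviation of additive Gaussian sensor
#'   noise, mV; `>= 0`.
#' @return an object of class `beat_params`.
#' @export
#' @examples
#' rest_beat_params()
beat_params <- function(mean_hr, sdnn_ms, respiratory_mod_hz = 0.25,
                        amplitude_mv = 1.0, noise_sd_mv = 0.05) {
  for (nm in c("mean_hr", "sdnn_ms", "respiratory_mod_hz",
               "amplitude_mv", "noise_sd_mv"))
    stopifnot_scalar_num(get(nm), nm)
  if (mean_hr < 30 || mean_hr > 220)
    abort("mean_hr must lie in [30, 220] beats/min, got %g", mean_hr)
  if (sdnn_ms < 0) abort("sdnn_ms must be >= 0")
  if (amplitude_mv <= 0) abort("amplitude_mv must be > 0")
  if (noise_sd_mv < 0) abort("noise_sd_mv must be >= 0")
  structure(list(mean_hr = mean_hr, sdnn_ms = sdnn_ms,
                 respiratory_mod_hz = respiratory_mod_hz,
                 amplitude_mv = amplitude_mv, noise_sd_mv = noise_sd_mv),
            class = "beat_params")
}

#' @rdname beat_params
#' @export
rest_beat_params <- function() beat_params(mean_hr = 65, sdnn_ms = 50)

#' @rdname beat_params
#' @export
stress_beat_params <- function() beat_params(mean_hr = 85, sdnn_ms = 25)

#' Experimental protocol specification
#'
#' An ordered sequence of rest/stress segments with durations and a
#' sampling rate, mirroring the two acquisition protocols: a laboratory
#' mental-arithmetic session (alternating 5-min rest and 5-min task blocks
#' at 256 Hz) and an ambulatory driving session (15-min rests flanking a
#' long driving block at 496 Hz).
#'
#' @param name `"mental_arithmetic"` or `"driving"`.
#' @param segments data.frame with columns `condition` (`"rest"`/`"stress"`)
#'   and `duration_s` (positive seconds).
#' @param fs sampling rate in Hz; one of 256 or 496.
#' @return an object of class `protocol_spec`.
#' @export
protocol_spec <- function(name = c("mental_arithmetic", "driving"),
                          segments, fs) {
  name <- match.arg(name)
  if (!is.data.frame(segments) ||
      !all(c("condition", "duration_s") %in% names(segments)))
    abort("segments must be a data.frame with 'condition' and 'duration_s'")
  if (!all(segments$condition %in% c("rest", "stress")))
    abort("segment conditions must be 'rest' or 'stress'")
  if (!all(segments$duration_s > 0)) abort("segment durations must be > 0")
  if (!fs %in% c(256, 496)) abort("fs must be 256 or 496 Hz, got %g", fs)
  if (name == "mental_arithmetic") {
    tot <- tapply(segments$duration_s, segments$condition, sum)
    if (!isTRUE(all.equal(unname(tot["rest"]), 600)) ||
        !isTRUE(all.equal(unname(tot["stress"]), 600)))
      abort("mental_arithmetic protocol must total 600 s rest and 600 s stress")
  } else {
    idx <- which(segments$condition == "stress")
    if (length(idx) == 0) abort("driving protocol needs a stress block")
    before <- sum(segments$duration_s[seq_len(min(idx) - 1)])
    after <- sum(segments$duration_s[seq(max(idx) + 1,
                                         length.out = nrow(segments) - max(idx))])
    if (before < 900 || after < 900)
      abort("driving protocol needs >= 15 min rest before and after driving")
  }
  structure(list(name = name,
                 segments = segments[, c("condition", "duration_s")],
                 fs = fs),
            class = "protocol_spec")
}

#' @rdname protocol_spec
#' @export
ma_protocol <- function() {
  protocol_spec("mental_arithmetic",
                data.frame(condition = c("rest", "stress", "rest", "stress"),
                           duration_s = rep(300, 4)),
                fs = 256)
}

#' @rdname protocol_spec
#' @param stress_min duration of the driving (stress) block in minutes;
#'   default 45, split into a city and a highway half.
#' @export
driving_protocol <- function(stress_min = 45) {
  stopifnot_scalar_num(stress_min, "stress_min")
  if (stress_min <= 0) abort("stress_min must be > 0")
  half <- stress_min * 60 / 2
  protocol_spec("driving",
                data.frame(condition = c("rest", "stress", "stress", "rest"),
                           duration_s = c(900, half, half, 900)),
                fs = 496)
}

#' Simulate an RR-interval series
#'
#' Draws successive RR intervals from a Gaussian around `60 / mean_hr`
#' seconds, with a sinusoidal respiratory modulation (30% of the RR
#' variance by default) plus independent Gaussian jitter, until the
#' cumulative time reaches `duration_s`. With `sdnn_ms = 0` the series is
#' exactly periodic.
#'
#' @param params a [beat_params()] object.
#' @param duration_s positive session duration in seconds.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return numeric vector of RR intervals in seconds whose cumulative sum
#'   is `>= duration_s`.
#' @export
#' @examples
#' rr <- simulate_rr_series(rest_beat_params(), 60, seed = 1)
simulate_rr_series <- function(params, duration_s, seed = NULL) {
  if (!inherits(params, "beat_params")) abort("params must be beat_params")
  stopifnot_scalar_num(duration_s, "duration_s")
  if (duration_s <= 0) abort("duration_s must be > 0, got %g", duration_s)
  gen <- function() {
    mu <- 60 / params$mean_hr
    sdnn <- params$sdnn_ms / 1000
    resp_frac <- 0.3                      # fraction of RR variance from RSA
    a <- sqrt(2 * resp_frac) * sdnn       # sinusoid amplitude
    s <- sqrt(1 - resp_frac) * sdnn       # residual Gaussian SD
    f <- params$respiratory_mod_hz
    n_guess <- ceiling(duration_s / mu * 1.3) + 16L
    z <- rnorm(n_guess)
    rr <- numeric(n_guess)
    t <- 0
    i <- 0L
    while (t < duration_s) {
      i <- i + 1L
      if (i > length(z)) z <- c(z, rnorm(n_guess))
      ri <- mu + a * sin(2 * pi * f * t) + s * z[i]
      ri <- max(ri, 0.25 * mu)            # physiologic floor
      rr[i] <- ri
      t <- t + ri
    }
    rr[seq_len(i)]
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# Gaussian P-QRS-T template: per-wave (offset from R apex, sd, relative
# amplitude), all in seconds / fraction of R amplitude.
pqrst_template <- function() {
  data.frame(wave = c("P", "Q", "R", "S", "T"),
             offset_s = c(-0.20, -0.03, 0.00, 0.03, 0.25),
             sd_s = c(0.040, 0.012, 0.018, 0.012, 0.060),
             amp_rel = c(0.15, -0.12, 1.00, -0.20, 0.35))
}

#' Synthesize an ECG sample vector from RR intervals
#'
#' Places a sum-of-Gaussians P-QRS-T beat template at the midpoint of each
#' RR interval and adds white Gaussian noise. The output has exactly
#' `round(sum(rr) * fs)` samples and one R apex per interval.
#'
#' @param rr RR intervals in seconds (may be empty).
#' @param fs sampling rate, Hz.
#' @param params a [beat_params()] object (amplitude and noise level).
#' @param seed optional integer seed for the noise.
#' @return numeric vector of ECG samples in mV.
#' @export
synthesize_ecg <- function(rr, fs, params, seed = NULL) {
  stopifnot_scalar_num(fs, "fs")
  if (fs <= 0) abort("fs must be > 0")
  if (!inherits(params, "beat_params")) abort("params must be beat_params")
  if (length(rr) == 0) return(numeric(0))
  if (any(rr <= 0)) abort("RR intervals must be positive")
  gen <- function() {
    total <- sum(rr)
    n <- round(total * fs)
    x <- numeric(n)
    beat_t <- cumsum(rr) - rr / 2
    tmpl <- pqrst_template()
    for (j in seq_along(beat_t)) {
      lo <- max(1L, floor((beat_t[j] - 0.5) * fs) + 1L)
      hi <- min(n, ceiling((beat_t[j] + 0.6) * fs) + 1L)
      if (lo > hi) next
      tt <- (seq(lo, hi) - 1) / fs - beat_t[j]
      acc <- numeric(hi - lo + 1L)
      for (w in seq_len(nrow(tmpl)))
        acc <- acc + tmpl$amp_rel[w] *
          exp(-0.5 * ((tt - tmpl$offset_s[w]) / tmpl$sd_s[w])^2)
      x[lo:hi] <- x[lo:hi] + params$amplitude_mv * acc
    }
    if (params$noise_sd_mv > 0) x <- x + rnorm(n, 0, params$noise_sd_mv)
    x
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Count R peaks by local-maximum scan
#'
#' Simple detector used to sanity-check synthetic signals: local maxima
#' above a threshold, with a refractory distance.
#'
#' @param x ECG samples (mV).
#' @param fs sampling rate (Hz).
#' @param threshold detection threshold (mV); default half the maximum.
#' @param refractory_s minimum peak spacing, s.
#' @return integer count of detected R peaks.
#' @export
count_r_peaks <- function(x, fs, threshold = 0.5 * max(x),
                          refractory_s = 0.2) {
  n <- length(x)
  if (n < 3) return(0L)
  is_max <- c(FALSE, x[2:(n - 1)] >= x[1:(n - 2)] &
                x[2:(n - 1)] > x[3:n], FALSE) & x > threshold
  cand <- which(is_max)
  if (length(cand) == 0) return(0L)
  keep <- cand[1]
  for (p in cand[-1]) if (p - keep[length(keep)] >= refractory_s * fs)
    keep <- c(keep, p)
  length(keep)
}

#' Simulate a multi-subject cohort of labeled ECG sessions
#'
#' Generates one [ecg_record()] per subject following a protocol, with
#' condition-specific beat parameters, deterministic per-subject seeds
#' derived from `cohort_seed`, and mild per-subject jitter (+/- 10%
#' uniform) on mean heart rate and SDNN. For the driving protocol the two
#' stress segments are labeled `stress_city` and `stress_highway`; the
#' mental-arithmetic task segments are labeled `stress_task`.
#'
#' @param protocol a [protocol_spec()].
#' @param n_subjects number of subjects (`>= 1`).
#' @param rest_params,stress_params [beat_params()] for each condition.
#' @param cohort_seed integer seed; identical inputs give bit-identical
#'   cohorts.
#' @return an object of class `synthetic_cohort`: list with `records`,
#'   `protocol`, `cohort_seed`.
#' @export
#' @examples
#' coh <- simulate_cohort(ma_protocol(), n_subjects = 2, cohort_seed = 7)
simulate_cohort <- function(protocol, n_subjects,
                            rest_params = rest_beat_params(),
                            stress_params = stress_beat_params(),
                            cohort_seed = 1L) {
  if (!inherits(protocol, "protocol_spec")) abort("protocol must be protocol_spec")
  stopifnot_scalar_num(n_subjects, "n_subjects")
  if (n_subjects < 1) abort("n_subjects must be >= 1")
  stressor <- if (protocol$name == "driving") "driving" else "mental_arithmetic"
  prefix <- if (stressor == "driving") "DR" else "MA"
  segs <- protocol$segments
  fs <- protocol$fs
  n_stress_seen <- 0L
  marker_cond <- character(nrow(segs))
  for (g in seq_len(nrow(segs))) {
    if (segs$condition[g] == "rest") marker_cond[g] <- "rest"
    else if (stressor == "mental_arithmetic") marker_cond[g] <- "stress_task"
    else {
      n_stress_seen <- n_stress_seen + 1L
      marker_cond[g] <- if (n_stress_seen %% 2L == 1L) "stress_city" else "stress_highway"
    }
  }
  ends <- cumsum(segs$duration_s)
  markers <- data.frame(condition = marker_cond,
                        start_s = c(0, ends[-length(ends)]),
                        end_s = ends)
  records <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("%s%02d", prefix, i)
    sseed <- derive_seed(cohort_seed, "subject", sid)
    jit <- with_seed(derive_seed(sseed, "jitter"), runif(2, 0.9, 1.1))
    subj_par <- function(p) beat_params(
      mean_hr = min(220, max(30, p$mean_hr * jit[1])),
      sdnn_ms = p$sdnn_ms * jit[2],
      respiratory_mod_hz = p$respiratory_mod_hz,
      amplitude_mv = p$amplitude_mv, noise_sd_mv = p$noise_sd_mv)
    pr <- subj_par(rest_params)
    ps <- subj_par(stress_params)
    samples <- vector("list", nrow(segs))
    for (g in seq_len(nrow(segs))) {
      p <- if (segs$condition[g] == "rest") pr else ps
      gseed <- derive_seed(sseed, "segment", g)
      rr <- simulate_rr_series(p, segs$duration_s[g], seed = gseed)
      x <- synthesize_ecg(rr, fs, p, seed = derive_seed(gseed, "noise"))
      n_target <- round(segs$duration_s[g] * fs)
      if (length(x) >= n_target) x <- x[seq_len(n_target)]
      else x <- c(x, numeric(n_target - length(x)))
      samples[[g]] <- x
    }
    records[[i]] <- ecg_record(subject_id = sid,
                               samples = unlist(samples, use.names = FALSE),
                               fs = fs, markers = markers,
                               stressor = stressor)
  }
  structure(list(records = records, protocol = protocol,
                 cohort_seed = cohort_seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %s, %d subjects, fs = %g Hz, %g s/record\n",
              x$protocol$name, length(x$records), x$protocol$fs,
              sum(x$protocol$segments$duration_s)))
  invisible(x)
}
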