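#' Detect beats on an AP-shaped (LEAP) trace
#'
#' Candidate beats are regions where the smoothed derivative exceeds an
#' adaptive threshold: `slope_fraction` (default 30%) of the
#' 95th percentile of per-block maximum slopes (blocks of one refractory
#' period), floored at 6 robust SDs of the slope trace so pure noise
#' yields no beats. Candidates closer than `refractory_ms` are merged.
#' The beat start is the earliest sample reaching the candidate's maximum
#' upstroke slope (within 0.5%), matching the "max slope of the rising
#' edge" convention while staying deterministic on linear upstrokes whose
#' slope is constant. Peaks and troughs are measured on the
#' Savitzky-Golay-smoothed trace; a partial beat at the end of the trace
#' (window shorter than 75% of the median beat period) is discarded.
#'
#' @param trace Numeric vector (uV), already band filtered.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param config An [analysis_config()].
#' @return An object of class `beat_train`: list with `starts_ms`,
#'   `start_idx`, `win_start`, `win_end` (per-beat sample windows),
#'   `peaks_uV`, `troughs_uV`, `amplitudes_uV`, `sampling_rate_hz`,
#'   `n_beats`. Zero-beat trains are valid.
#' @export
detect_beats_ap <- function(trace, sampling_rate_hz,
                            config = analysis_config()) {
  if (length(trace) == 0) stop("empty trace")
  fs <- sampling_rate_hz
  slope <- sg_slope(trace, fs, config$smooth_ms)
  thr <- adaptive_threshold(slope, stats::mad(slope), fs,
                            config$refractory_ms, config$slope_fraction)
  candidate_beats(trace, slope, thr, fs, config,
                  start_rule = "max_slope")
}

#' Detect beats on an FP trace
#'
#' Beats are located at depolarization spikes: the largest absolute
#' deflections above an adaptive threshold (same construction as
#' [detect_beats_ap()], applied to the absolute deviation from the
#' median), separated by the refractory period. The beat start is the
#' spike extremum time.
#'
#' @inheritParams detect_beats_ap
#' @return A `beat_train` (see [detect_beats_ap()]).
#' @export
detect_beats_fp <- function(trace, sampling_rate_hz,
                            config = analysis_config()) {
  if (length(trace) == 0) stop("empty trace")
  fs <- sampling_rate_hz
  dev <- abs(trace - stats::median(trace))
  # spikes are the dominant deflection of an FP, so a higher fraction than
  # the AP slope detector keeps the repolarization wave out
  thr <- adaptive_threshold(dev, stats::mad(trace), fs,
                            config$refractory_ms, 0.5)
  candidate_beats(trace, dev, thr, fs, config, start_rule = "extremum")
}

# Threshold = fraction of the 95th percentile of per-block maxima,
# floored at 6 robust SDs of the score noise so noise-only traces yield
# no candidates.
adaptive_threshold <- function(score, sigma, fs, refractory_ms, fraction) {
  n <- length(score)
  block <- max(1L, round(refractory_ms / 1000 * fs))
  nb <- max(1L, n %/% block)
  bm <- vapply(seq_len(nb), function(i) {
    max(score[((i - 1) * block + 1):min(i * block, n)])
  }, numeric(1))
  s_ref <- stats::quantile(bm, 0.95, names = FALSE)
  max(fraction * s_ref, 6 * sigma, .Machine$double.eps)
}

candidate_beats <- function(trace, score, thr, fs, config, start_rule) {
  n <- length(trace)
  dt_ms <- 1000 / fs
  refr <- round(config$refractory_ms / dt_ms)
  above <- score > thr
  if (!any(above)) return(empty_beat_train(fs))
  d <- diff(c(FALSE, above, FALSE))
  run_start <- which(d == 1L)
  run_end <- which(d == -1L) - 1L
  # merge runs separated by less than the refractory period
  if (length(run_start) > 1) {
    keep <- c(TRUE, run_start[-1] - run_end[-length(run_end)] > refr)
    grp <- cumsum(keep)
    run_start <- tapply(run_start, grp, min)
    run_end <- tapply(run_end, grp, max)
  }
  run_start <- as.integer(run_start)
  run_end <- as.integer(run_end)
  starts <- integer(0)
  for (k in seq_along(run_start)) {
    seg <- run_start[k]:run_end[k]
    idx <- seg[which.max(score[seg])]
    if (length(starts) == 0 || idx - starts[length(starts)] > refr) {
      starts <- c(starts, idx)
    }
  }
  starts_ms <- (starts - 1L) * dt_ms
  if (start_rule == "max_slope") {
    starts_ms <- vapply(starts, refine_beat_start, numeric(1),
                        trace = trace, fs = fs, refr = refr)
    starts <- pmax(1L, pmin(n, as.integer(round(starts_ms / dt_ms)) + 1L))
  }
  build_beat_train(trace, starts, starts_ms, fs, config,
                   pre_ms = if (start_rule == "max_slope") 20 else 10)
}

# Sub-sample localization of the beat-start fiducial. The maximum-slope
# sample of a near-linear upstroke is ill-determined under noise (the
# slope is constant along the edge), so the fiducial is pinned to the
# half-amplitude crossing of the rising edge, which coincides with the
# midpoint of the maximum-slope region and has noise jitter
# sigma / slope (sub-sample for any usable SNR).
refine_beat_start <- function(idx, trace, fs, refr) {
  n <- length(trace)
  dt_ms <- 1000 / fs
  lo <- max(1L, idx - refr %/% 2L)
  hi <- min(n, idx + refr)
  peak_i <- idx + which.max(trace[idx:hi]) - 1L
  trough <- min(trace[lo:idx])
  half <- (trace[peak_i] + trough) / 2
  # last upward crossing of the half level before the peak
  seg <- lo:peak_i
  below <- which(trace[seg] < half)
  if (length(below) == 0) return((idx - 1L) * dt_ms)
  j <- seg[below[length(below)]]
  if (j >= n) return((j - 1L) * dt_ms)
  v0 <- trace[j]; v1 <- trace[j + 1L]
  frac <- if (v1 > v0) (half - v0) / (v1 - v0) else 0
  (j - 1L + frac) * dt_ms
}

empty_beat_train <- function(fs) {
  structure(list(starts_ms = numeric(0), start_idx = integer(0),
                 win_start = integer(0), win_end = integer(0),
                 pre_samples = 0L,
                 peaks_uV = numeric(0), troughs_uV = numeric(0),
                 amplitudes_uV = numeric(0), sampling_rate_hz = fs,
                 n_beats = 0L),
            class = "beat_train")
}

build_beat_train <- function(trace, starts, starts_ms, fs, config,
                             pre_ms = 0) {
  n <- length(trace)
  dt_ms <- 1000 / fs
  nb <- length(starts)
  if (nb == 0) return(empty_beat_train(fs))
  if (nb >= 2) {
    med_win <- stats::median(diff(starts))
    win_end <- c(starts[-1] - 1L, min(n, starts[nb] + round(med_win)))
    # partial beat at the trace edge
    if ((win_end[nb] - starts[nb] + 1L) < 0.75 * med_win) {
      starts <- starts[-nb]
      starts_ms <- starts_ms[-nb]
      win_end <- win_end[-nb]
      nb <- nb - 1L
    }
  } else {
    win_end <- n
  }
  # pre-roll before the beat-start fiducial so the full upstroke
  # (take-off point included) lies inside the window; a beat too close to
  # the trace edge gets a clipped window and is skipped when averaging
  pre <- max(0L, as.integer(round(pre_ms / dt_ms)))
  win_start <- pmax(1L, starts - pre)
  # peak/trough on a running-median-smoothed trace: robust to noise
  # without polynomial overshoot at waveform corners
  sm <- med_smooth(trace, fs, 5)
  peaks <- troughs <- numeric(nb)
  for (i in seq_len(nb)) {
    w <- sm[starts[i]:win_end[i]]
    peaks[i] <- max(w)
    troughs[i] <- min(w)
  }
  structure(list(starts_ms = starts_ms,
                 start_idx = as.integer(starts),
                 win_start = as.integer(win_start),
                 win_end = as.integer(win_end),
                 pre_samples = pre,
                 peaks_uV = peaks, troughs_uV = troughs,
                 amplitudes_uV = peaks - troughs,
                 sampling_rate_hz = fs, n_beats = nb),
            class = "beat_train")
}

#' @export
print.beat_train <- function(x, ...) {
  cat(sprintf("beat_train: %d beats", x$n_beats))
  if (x$n_beats >= 2) {
    cat(sprintf(", mean BP %.1f ms", mean(diff(x$starts_ms))))
  }
  cat("\n")
  invisible(x)
}

#' Classify an electrode signal as LEAP, FP or quiescent
#'
#' The trace is filtered with the LEAP acquisition band and beats are
#' detected (AP detector first, spike detector as fallback). A trace with
#' no detectable beats is `QUIESCENT`. Otherwise the signal is `LEAP`
#' when its standard deviation exceeds `sd_uV` (default 100 uV) and its
#' amplitude -- the median per-beat peak-to-trough -- exceeds `amp_uV`
#' (default 350 uV); anything else is `FP`.
#'
#' @inheritParams detect_beats_ap
#' @return A list of class `signal_class` with elements `class` (one of
#'   `"LEAP"`, `"FP"`, `"QUIESCENT"`), `sd_uV`, `amplitude_uV`, and the
#'   `beat_train` used.
#' @export
classify_signal <- function(trace, sampling_rate_hz,
                            config = analysis_config()) {
  if (length(trace) == 0) stop("empty trace")
  fs <- sampling_rate_hz
  band <- effective_band(fs, config$leap_band[1], config$leap_band[2])
  x <- bandpass(trace, fs, band["low"], band["high"])
  beats <- detect_beats_ap(x, fs, config)
  if (beats$n_beats == 0) beats <- detect_beats_fp(x, fs, config)
  if (beats$n_beats == 0) {
    return(structure(list(class = "QUIESCENT", sd_uV = stats::sd(x),
                          amplitude_uV = NA_real_, beats = beats,
                          filtered = x),
                     class = "signal_class"))
  }
  amp <- stats::median(beats$amplitudes_uV)
  if (!is.finite(amp)) amp <- max(x) - min(x)
  cls <- if (stats::sd(x) > config$sd_uV && amp > config$amp_uV) {
    "LEAP"
  } else {
    "FP"
  }
  structure(list(class = cls, sd_uV = stats::sd(x), amplitude_uV = amp,
                 beats = beats, filtered = x),
            class = "signal_class")
}

#' Segment, normalize and average beats into a waveform template
#'
#' Each beat window is amplitude normalized from zero (trough) to one
#' (peak), aligned on the beat start, truncated to the common window
#' length, and averaged pointwise over the first
#' `min(n_beats, available)` beats. The averaged waveform is rescaled so
#' its minimum is exactly 0 and its maximum exactly 1.
#'
#' @param trace Numeric vector (uV).
#' @param beats A `beat_train` from [detect_beats_ap()].
#' @param n_beats Number of beats to average (default 5).
#' @param config An [analysis_config()].
#' @return An object of class `waveform_template`: list with `samples`
#'   (unitless, in `[0, 1]`), `sampling_rate_hz`, `n_beats` (number
#'   averaged), `beat_start_idx` (sample index of the beat-start fiducial
#'   within the template; windows carry a short pre-roll so the take-off
#'   point is retained), `amplitude_uV` (median source beat amplitude).
#' @export
segment_normalize_average <- function(trace, beats, n_beats = 5,
                                      config = analysis_config()) {
  stopifnot(inherits(beats, "beat_train"))
  if (beats$n_beats < 1) stop("no beats to average")
  fs <- beats$sampling_rate_hz
  # only beats whose full pre-roll is inside the trace align exactly
  full <- which(beats$start_idx - beats$win_start == beats$pre_samples)
  if (length(full) == 0) full <- seq_len(beats$n_beats)
  use <- full[seq_len(min(n_beats, length(full)))]
  len <- min(beats$win_end[use] - beats$win_start[use] + 1L)
  if (beats$n_beats >= 2) {
    med_bp <- stats::median(diff(beats$start_idx))
    len <- min(len, as.integer(round(med_bp)))
  }
  acc <- numeric(len)
  for (i in use) {
    w <- trace[beats$win_start[i]:(beats$win_start[i] + len - 1L)]
    rng <- beats$peaks_uV[i] - beats$troughs_uV[i]
    if (rng <= 0) stop("constant (zero-amplitude) beat window")
    acc <- acc + (w - beats$troughs_uV[i]) / rng
  }
  avg <- acc / length(use)
  avg <- (avg - min(avg)) / (max(avg) - min(avg))
  structure(list(samples = avg, sampling_rate_hz = fs,
                 n_beats = length(use),
                 beat_start_idx = beats$pre_samples + 1L,
                 amplitude_uV = stats::median(beats$amplitudes_uV[use])),
            class = "waveform_template")
}

#' Select the electrode carrying the best LEAP signal in a well
#'
#' Among LEAP-class electrodes, the one with the largest median beat
#' amplitude wins; ties go to the lowest electrode index. Returns `NA`
#' when no electrode in the well classifies as LEAP.
#'
#' @param traces Matrix of traces (samples x electrodes) for one well.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param config An [analysis_config()].
#' @return Integer column index of the chosen electrode, or `NA_integer_`.
#' @export
select_best_electrode <- function(traces, sampling_rate_hz,
                                  config = analysis_config()) {
  stopifnot(is.matrix(traces))
  if (ncol(traces) == 0) stop("empty well")
  amps <- rep(-Inf, ncol(traces))
  for (j in seq_len(ncol(traces))) {
    cl <- classify_signal(traces[, j], sampling_rate_hz, config)
    if (cl$class == "LEAP") amps[j] <- cl$amplitude_uV
  }
  if (all(!is.finite(amps))) return(NA_integer_)
  which.max(amps)  # ties resolve to the lowest index
}
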