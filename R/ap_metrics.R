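#' Action potential duration at given repolarization percentages
#'
#' The repolarization fraction is defined peak-to-trough:
#' `r(t) = (V_peak - V(t)) / (V_peak - V_trough)`. `APD_x` is the time
#' from beat start to the first post-peak crossing of `r >= x/100`,
#' linearly interpolated between samples for sub-sample precision.
#'
#' @param wave Numeric vector: one beat (or averaged template), aligned so
#'   that the beat start is at `beat_start_idx`.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param percentages Repolarization percentages in (0, 100); default
#'   `c(30, 50, 90)`.
#' @param beat_start_idx Sample index of the beat start (default 1, the
#'   convention of [segment_normalize_average()] windows).
#' @return Named numeric vector of APDs in ms (`NA` where the waveform
#'   never reaches the requested repolarization).
#' @export
compute_apd <- function(wave, sampling_rate_hz,
                        percentages = c(30, 50, 90),
                        beat_start_idx = 1L) {
  stopifnot(length(wave) >= 2, sampling_rate_hz > 0)
  if (any(percentages <= 0 | percentages >= 100)) {
    stop("percentages must lie strictly between 0 and 100")
  }
  dt_ms <- 1000 / sampling_rate_hz
  i_peak <- which.max(wave)
  v_peak <- wave[i_peak]
  v_trough <- min(wave[i_peak:length(wave)])
  if (v_peak <= v_trough) stop("waveform has no repolarization limb")
  r <- (v_peak - wave) / (v_peak - v_trough)
  out <- stats::setNames(rep(NA_real_, length(percentages)),
                         paste0("apd", percentages))
  for (k in seq_along(percentages)) {
    x <- percentages[k] / 100
    post <- i_peak:length(wave)
    j <- post[which(r[post] >= x)[1]]
    if (is.na(j)) next
    if (j == i_peak) {
      t_cross <- (j - 1) * dt_ms
    } else {
      # linear interpolation between the bracketing samples
      r0 <- r[j - 1]; r1 <- r[j]
      frac <- if (r1 > r0) (x - r0) / (r1 - r0) else 0
      t_cross <- (j - 2 + frac) * dt_ms
    }
    out[k] <- t_cross - (beat_start_idx - 1) * dt_ms
  }
  out
}

#' Full APD curve from 0 to 90 percent repolarization
#'
#' @inheritParams compute_apd
#' @param step Percent step of the curve grid (default 10).
#' @return Data frame with columns `pct` and `apd_ms`.
#' @export
apd_curve <- function(wave, sampling_rate_hz, step = 10,
                      beat_start_idx = 1L) {
  pct <- seq(step, 90, by = step)
  data.frame(pct = pct,
             apd_ms = unname(compute_apd(wave, sampling_rate_hz, pct,
                                         beat_start_idx)))
}

#' Rise time of the AP upstroke
#'
#' The take-off point is the last time before the maximum-slope sample at
#' which the smoothed derivative falls below `takeoff_fraction` (default
#' 10%) of the beat's maximum slope; rise time is the interval from
#' take-off to the waveform peak.
#'
#' @inheritParams compute_apd
#' @param config An [analysis_config()] (supplies `takeoff_fraction` and
#'   the smoothing window).
#' @return Rise time in ms.
#' @export
compute_rise_time <- function(wave, sampling_rate_hz,
                              config = analysis_config()) {
  stopifnot(length(wave) >= 3)
  dt_ms <- 1000 / sampling_rate_hz
  slope <- sg_slope(wave, sampling_rate_hz, config$smooth_ms)
  # peak fiducial: first sample within 1% of the maximum, so that noise on
  # a flat-topped AP does not drag the apparent peak into the plateau
  sm <- med_smooth(wave, sampling_rate_hz, config$smooth_ms)
  rng <- max(sm) - min(sm)
  if (rng <= 0) stop("waveform has no upstroke")
  i_peak <- which(sm >= max(sm) - 0.01 * rng)[1]
  if (i_peak == 1 || max(slope[seq_len(i_peak)]) <= 0) {
    stop("waveform has no upstroke")
  }
  i_ms <- which.max(slope[seq_len(i_peak)])
  below <- which(slope[seq_len(i_ms)] < config$takeoff_fraction * slope[i_ms])
  i_take <- if (length(below)) below[length(below)] else 1L
  (i_peak - i_take) * dt_ms
}

#' Beat period statistics
#'
#' Beat periods are the differences between consecutive beat starts; the
#' coefficient of variation uses the sample SD (n-1 denominator).
#'
#' @param beats A `beat_train` (or numeric vector of beat-start times in
#'   ms).
#' @return List with `mean_bp_ms`, `cov_percent`, `n_intervals`, or `NA`
#'   fields plus a `reason` when fewer than 3 beats are available.
#' @export
compute_bp_cov <- function(beats) {
  starts <- if (inherits(beats, "beat_train")) beats$starts_ms else beats
  if (length(starts) < 3) {
    return(list(mean_bp_ms = NA_real_, cov_percent = NA_real_,
                n_intervals = length(starts) - 1L,
                reason = "fewer than 3 beats"))
  }
  bp <- diff(starts)
  m <- mean(bp)
  list(mean_bp_ms = m, cov_percent = 100 * stats::sd(bp) / m,
       n_intervals = length(bp), reason = NULL)
}

#' Triangulation ratio APD50/APD90
#'
#' 1 corresponds to a perfectly square AP, values near 5/9 to a perfect
#' triangle; a decrease indicates increased triangulation of the
#' repolarization phase (higher arrhythmogenic risk).
#'
#' @param apd50,apd90 APDs in ms, `apd50 <= apd90`, `apd90 > 0`.
#' @return Dimensionless ratio in (0, 1].
#' @export
triangulation_ratio <- function(apd50, apd90) {
  if (any(is.na(apd50)) || any(is.na(apd90))) return(NA_real_)
  stopifnot(apd90 > 0)
  if (apd50 > apd90) stop("apd50 > apd90 violates APD monotonicity")
  apd50 / apd90
}

#' Detect early afterdepolarizations on one beat
#'
#' EADs are local maxima strictly between the depolarization peak and the
#' time of 90% repolarization whose topographic prominence -- height
#' above the greater of the two flanking minima within the repolarization
#' limb -- satisfies both `prominence >= ead_abs_uV` (default 20 uV) and
#' `prominence > ead_frac * leap_amplitude_uV` (default 2.5%). The beat
#' is lightly smoothed before peak finding so single noise samples do not
#' register as peaks.
#'
#' @param wave Numeric vector: one un-normalized beat in uV, starting at
#'   the beat start.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param leap_amplitude_uV Peak-to-trough LEAP amplitude of the signal
#'   (uV).
#' @param config An [analysis_config()].
#' @return Data frame with one row per event: `time_ms` (from beat
#'   start), `prominence_uV`.
#' @export
detect_eads <- function(wave, sampling_rate_hz, leap_amplitude_uV,
                        config = analysis_config()) {
  stopifnot(length(wave) >= 3, leap_amplitude_uV > 0)
  dt_ms <- 1000 / sampling_rate_hz
  sm <- med_smooth(wave, sampling_rate_hz, config$smooth_ms)
  # depolarization peak: the crest right after the upstroke, not the
  # global maximum (a large EAD on the plateau could exceed the latter)
  rng <- max(sm) - min(sm)
  if (rng <= 0) stop("beat lacks a repolarization limb")
  i0 <- which(sm - min(sm) >= 0.90 * rng)[1]
  i1 <- min(length(sm), i0 + round(5 / dt_ms))
  i_peak <- i0 + which.max(sm[i0:i1]) - 1L
  v_peak <- sm[i_peak]
  v_trough <- min(sm[i_peak:length(sm)])
  if (v_peak <= v_trough) stop("beat lacks a repolarization limb")
  r <- (v_peak - sm) / (v_peak - v_trough)
  post <- i_peak:length(sm)
  j90 <- post[which(r[post] >= 0.9)[1]]
  if (is.na(j90) || j90 - i_peak < 3) {
    return(data.frame(time_ms = numeric(0), prominence_uV = numeric(0)))
  }
  seg <- sm[i_peak:j90]
  n <- length(seg)
  d <- diff(seg)
  # strict local maxima of the smoothed repolarization limb
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[cand > 1 & cand < n]
  times <- proms <- numeric(0)
  for (m in cand) {
    left_min <- min(seg[1:m])
    right_min <- min(seg[m:n])
    prom <- seg[m] - max(left_min, right_min)
    if (prom >= config$ead_abs_uV &&
        prom > config$ead_frac * leap_amplitude_uV) {
      times <- c(times, (i_peak + m - 2) * dt_ms)
      proms <- c(proms, prom)
    }
  }
  data.frame(time_ms = times, prominence_uV = proms)
}

#' Percentage of beats carrying at least one EAD
#'
#' @param n_beats Number of analyzed beats (> 0).
#' @param beats_with_eads Number of beats with at least one detected EAD.
#' @return Percentage in `[0, 100]`.
#' @export
percent_beats_with_eads <- function(n_beats, beats_with_eads) {
  if (n_beats < 1) stop("empty beat train")
  100 * beats_with_eads / n_beats
}
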