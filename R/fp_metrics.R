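#' FP depolarization spike amplitude
#'
#' Peak-to-trough voltage within +/- 10 ms of the spike extremum. No
#' smoothing is applied: the band-limited spike is sharp, so the
#' max-of-noise inflation is negligible, whereas smoothing would shave
#' the narrow spike valley itself.
#'
#' @param wave Numeric vector: one FP beat window (uV).
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param spike_idx Sample index of the spike extremum within `wave`
#'   (default 1; [detect_beats_fp()] windows place it at
#'   `pre_samples + 1`).
#' @return Spike amplitude in uV.
#' @export
compute_fp_amplitude <- function(wave, sampling_rate_hz, spike_idx = 1L) {
  if (length(wave) == 0) stop("empty beat window")
  dt_ms <- 1000 / sampling_rate_hz
  half <- round(10 / dt_ms)
  seg <- wave[max(1L, spike_idx - half):min(length(wave), spike_idx + half)]
  max(seg) - min(seg)
}

#' Field potential duration
#'
#' FPD is the time from the depolarization spike extremum to the extremum
#' of the repolarization feature: the largest absolute deflection (from
#' the window median) in the search window from `fpd_min_ms` (default
#' 100 ms) to 90% of the beat period after the spike. Polarity of the
#' repolarization feature is not assumed; ties go to the earlier time.
#' When no deflection exceeds the noise floor the feature is declared not
#' detectable and `NA` is returned with reason `"ND"`. The noise floor is
#' `max(6 sigma, fpd_floor_uV)` with sigma estimated from first
#' differences (`mad(diff(wave)) / sqrt(2)`), so a broad repolarization
#' wave does not inflate its own detection floor.
#'
#' @param wave One FP beat window (uV).
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param bp_ms Beat period (ms) bounding the search window.
#' @param config An [analysis_config()].
#' @param spike_idx Sample index of the spike extremum within `wave`.
#' @return List with `fpd_ms` (`NA` when not detectable) and `reason`
#'   (`NULL` or `"ND"`).
#' @export
compute_fpd <- function(wave, sampling_rate_hz, bp_ms,
                        config = analysis_config(), spike_idx = 1L) {
  if (length(wave) == 0) stop("empty beat window")
  dt_ms <- 1000 / sampling_rate_hz
  sm <- med_smooth(wave, sampling_rate_hz, config$smooth_ms)
  base <- stats::median(sm)
  i0 <- spike_idx + round(config$fpd_min_ms / dt_ms)
  i1 <- min(length(sm), spike_idx + round(0.9 * bp_ms / dt_ms) - 1L)
  if (i0 >= i1) return(list(fpd_ms = NA_real_, reason = "ND"))
  dev <- abs(sm[i0:i1] - base)
  sigma <- stats::mad(diff(wave)) / sqrt(2)
  floor_uV <- max(6 * sigma, config$fpd_floor_uV)
  j <- which.max(dev)                     # which.max takes the earliest tie
  if (dev[j] <= floor_uV) return(list(fpd_ms = NA_real_, reason = "ND"))
  list(fpd_ms = (i0 + j - 1L - spike_idx) * dt_ms, reason = NULL)
}

#' Fridericia rate correction
#'
#' `FPDc = FPD / (BP in seconds)^(1/3)`: the standard cube-root
#' correction referencing durations to a 1 s beat period.
#'
#' @param fpd_ms Field potential duration (ms, > 0).
#' @param bp_ms Beat period (ms, > 0).
#' @return Corrected duration FPDc in ms.
#' @examples
#' fridericia_correct(240, 512)  # 0.512^(1/3) = 0.8, so 300 ms
#' @export
fridericia_correct <- function(fpd_ms, bp_ms) {
  if (any(fpd_ms <= 0, na.rm = TRUE) || any(bp_ms <= 0, na.rm = TRUE)) {
    stop("fpd_ms and bp_ms must be positive")
  }
  fpd_ms / (bp_ms / 1000)^(1 / 3)
}

#' Percent change from baseline
#'
#' @param baseline Baseline value (non-zero).
#' @param post Post-treatment value.
#' @return `100 * (post - baseline) / baseline`.
#' @export
percent_change <- function(baseline, post) {
  if (any(baseline == 0)) stop("zero baseline")
  100 * (post - baseline) / baseline
}
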