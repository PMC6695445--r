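#' Analysis configuration
#'
#' All thresholds and detector settings used by the pipeline, with the
#' acquisition-derived defaults: FP band 1-2000 Hz, LEAP band
#' 0.01-2000 Hz, LEAP classification thresholds of 100 uV trace SD and
#' 350 uV beat amplitude, EAD thresholds of 20 uV absolute and 2.5% of
#' the LEAP amplitude, and averaging over 5 beats.
#'
#' @param fp_band Band edges (Hz) for FP-mode filtering.
#' @param leap_band Band edges (Hz) for LEAP-mode filtering.
#' @param sd_uV LEAP classification: minimum trace standard deviation.
#' @param amp_uV LEAP classification: minimum beat amplitude.
#' @param ead_abs_uV EAD rule: minimum peak prominence in uV.
#' @param ead_frac EAD rule: minimum prominence as a fraction of the LEAP
#'   amplitude.
#' @param beats_to_average Number of beats averaged into a waveform
#'   template.
#' @param refractory_ms Minimum separation between detected beats.
#' @param slope_fraction Adaptive beat-detection threshold as a fraction
#'   of the 95th-percentile upstroke slope.
#' @param takeoff_fraction Rise-time take-off point: fraction of the max
#'   upstroke slope below which the upstroke has not yet begun.
#' @param smooth_ms Savitzky-Golay window (ms) for slope estimation and
#'   peak/trough measurement.
#' @param fpd_min_ms Earliest time after the spike at which the FP
#'   repolarization feature is searched for.
#' @param fpd_floor_uV Absolute noise floor below which no repolarization
#'   feature is reported.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(fp_band = c(1, 2000),
                            leap_band = c(0.01, 2000),
                            sd_uV = 100,
                            amp_uV = 350,
                            ead_abs_uV = 20,
                            ead_frac = 0.025,
                            beats_to_average = 5,
                            refractory_ms = 250,
                            slope_fraction = 0.30,
                            takeoff_fraction = 0.10,
                            smooth_ms = 2,
                            fpd_min_ms = 100,
                            fpd_floor_uV = 2) {
  stopifnot(length(fp_band) == 2, length(leap_band) == 2,
            fp_band[1] >= 0, fp_band[1] < fp_band[2],
            leap_band[1] >= 0, leap_band[1] < leap_band[2],
            sd_uV > 0, amp_uV > 0, ead_abs_uV > 0, ead_frac > 0,
            beats_to_average >= 1, refractory_ms > 0,
            slope_fraction > 0, slope_fraction < 1,
            takeoff_fraction > 0, takeoff_fraction < 1)
  structure(list(fp_band = fp_band, leap_band = leap_band, sd_uV = sd_uV,
                 amp_uV = amp_uV, ead_abs_uV = ead_abs_uV,
                 ead_frac = ead_frac, beats_to_average = beats_to_average,
                 refractory_ms = refractory_ms,
                 slope_fraction = slope_fraction,
                 takeoff_fraction = takeoff_fraction, smooth_ms = smooth_ms,
                 fpd_min_ms = fpd_min_ms, fpd_floor_uV = fpd_floor_uV),
            class = "analysis_config")
}
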