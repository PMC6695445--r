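# Zero-phase running mean via cumulative sums; shrinks the window near the
# edges so no padding artifacts are introduced.
zero_phase_running_mean <- function(x, window) {
  n <- length(x)
  if (window >= n) {
    # a window spanning the trace cannot resolve any baseline structure;
    # a constant mean avoids edge-shrinkage tilt
    return(rep(mean(x), n))
  }
  window <- max(1L, as.integer(window))
  half <- window %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Zero-phase band filtering
#'
#' Applies the acquisition band to a trace with no group delay. The low
#' edge is implemented as subtraction of a zero-phase running-mean
#' baseline with window `1 / low_hz` seconds (exact DC removal, unity gain
#' in the passband); the high edge is a 2nd-order Butterworth low-pass
#' applied forward and backward (`signal::filtfilt`; 4th-order magnitude,
#' zero phase). A low edge of 0 disables baseline removal.
#'
#' @param trace Numeric vector (uV).
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param low_hz Low band edge (Hz, >= 0).
#' @param high_hz High band edge (Hz); must satisfy
#'   `low_hz < high_hz < sampling_rate_hz / 2`.
#' @return Filtered trace, same length.
#' @export
bandpass <- function(trace, sampling_rate_hz, low_hz = 1, high_hz = 2000) {
  stopifnot(is.numeric(trace), sampling_rate_hz > 0)
  nyq <- sampling_rate_hz / 2
  if (low_hz < 0 || high_hz <= low_hz || high_hz >= nyq) {
    stop("band edges must satisfy 0 <= low_hz < high_hz < Nyquist (",
         nyq, " Hz)")
  }
  x <- trace
  if (low_hz > 0) {
    x <- x - zero_phase_running_mean(x, round(sampling_rate_hz / low_hz))
  }
  if (high_hz < 0.4 * sampling_rate_hz) {
    # an edge at >= 80% of Nyquist would only add ringing; leave the trace
    # untouched there
    bf <- signal::butter(2, high_hz / nyq, type = "low")
    x <- signal::filtfilt(bf, x)
  }
  x
}

# Band edges capped to the recording's Nyquist range, for use by the
# pipeline when a configured band exceeds what the sampling rate supports.
effective_band <- function(sampling_rate_hz, low_hz, high_hz) {
  c(low = low_hz, high = min(high_hz, 0.45 * sampling_rate_hz))
}

# Savitzky-Golay smoothing; window is chosen in ms and converted to an odd
# sample count (minimum 5). Falls back to the identity for very short
# traces.
sg_window <- function(sampling_rate_hz, window_ms) {
  w <- round(window_ms * sampling_rate_hz / 1000)
  w <- max(5L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  w
}

sg_smooth <- function(x, sampling_rate_hz, window_ms = 2) {
  w <- sg_window(sampling_rate_hz, window_ms)
  if (length(x) <= w) return(x)
  signal::sgolayfilt(x, p = 3, n = w)
}

# Running-median smoothing for level (peak/trough) measurement: unlike a
# polynomial filter it cannot overshoot at waveform corners, and it is
# unbiased wherever the waveform is locally flat.
med_smooth <- function(x, sampling_rate_hz, window_ms = 5) {
  k <- round(window_ms * sampling_rate_hz / 1000)
  k <- max(3L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (length(x) <= k) return(x)
  as.numeric(stats::runmed(x, k, endrule = "keep"))
}

# Smoothed first derivative in uV/ms.
sg_slope <- function(x, sampling_rate_hz, window_ms = 2) {
  w <- sg_window(sampling_rate_hz, window_ms)
  if (length(x) <= w) return(c(diff(x), 0) * sampling_rate_hz / 1000)
  signal::sgolayfilt(x, p = 3, n = w, m = 1) * sampling_rate_hz / 1000
}
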