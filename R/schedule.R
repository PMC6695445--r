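#' Describe the beat timing of an electrode
#'
#' Spontaneous mode draws inter-beat intervals from a truncated normal
#' distribution with mean `mean_bp_ms` and standard deviation
#' `cov_percent / 100 * mean_bp_ms` (floored at `floor_ms`, modelling
#' refractoriness). Paced mode uses an explicit stimulus train and assumes
#' capture whenever the stimulus interval exceeds the refractory floor.
#'
#' @param mode `"spontaneous"` or `"paced"`.
#' @param mean_bp_ms Mean beat period (ms, > 0).
#' @param cov_percent Beat-period coefficient of variation in percent
#'   (spontaneous mode; >= 0).
#' @param stimulus_times_ms Strictly increasing stimulus times (paced mode).
#' @param adaptation_beats Number of beats over which APD relaxes toward
#'   its rate-dependent steady state (see [restitution_map()]).
#' @param floor_ms Smallest admissible inter-beat interval (ms).
#' @return An object of class `beat_schedule`.
#' @export
beat_schedule <- function(mode = c("spontaneous", "paced"),
                          mean_bp_ms = 1000,
                          cov_percent = 1,
                          stimulus_times_ms = NULL,
                          adaptation_beats = 25,
                          floor_ms = 100) {
  mode <- match.arg(mode)
  stopifnot(mean_bp_ms > 0, cov_percent >= 0, adaptation_beats >= 1,
            floor_ms > 0)
  if (mode == "paced") {
    if (is.null(stimulus_times_ms) || length(stimulus_times_ms) < 1) {
      stop("paced mode requires stimulus_times_ms")
    }
    if (any(diff(stimulus_times_ms) <= 0)) {
      stop("stimulus_times_ms must be strictly increasing")
    }
  }
  structure(
    list(mode = mode, mean_bp_ms = mean_bp_ms, cov_percent = cov_percent,
         stimulus_times_ms = stimulus_times_ms,
         adaptation_beats = adaptation_beats, floor_ms = floor_ms),
    class = "beat_schedule")
}

#' Generate beat-start times for a schedule
#'
#' @param schedule A [beat_schedule()].
#' @param duration_s Recording duration in seconds (> 0).
#' @param seed Optional integer seed; when given, results are reproducible
#'   bit-for-bit.
#' @return Strictly increasing beat-start times in ms, beginning at 0 for
#'   spontaneous trains. Intervals below the refractory floor are rejected
#'   and redrawn; an error is raised if the rejection rate exceeds 50%.
#' @export
generate_beat_times <- function(schedule, duration_s, seed = NULL) {
  stopifnot(inherits(schedule, "beat_schedule"), duration_s > 0)
  dur_ms <- duration_s * 1000
  if (schedule$mode == "paced") {
    st <- schedule$stimulus_times_ms
    return(st[st < dur_ms])
  }
  if (!is.null(seed)) set.seed(seed)
  mu <- schedule$mean_bp_ms
  sdv <- schedule$cov_percent / 100 * mu
  n_max <- ceiling(dur_ms / max(mu - 3 * sdv, schedule$floor_ms)) + 10L
  if (sdv == 0) {
    iv <- rep(mu, n_max)
  } else {
    iv <- stats::rnorm(n_max, mu, sdv)
    n_tot <- n_max
    bad <- which(iv < schedule$floor_ms)
    guard <- 0L
    while (length(bad) > 0 && guard < 50L) {
      n_tot <- n_tot + length(bad)
      iv[bad] <- stats::rnorm(length(bad), mu, sdv)
      bad <- which(iv < schedule$floor_ms)
      guard <- guard + 1L
    }
    if ((n_tot - n_max) / n_tot > 0.5) {
      stop("beat-interval rejection rate exceeds 50%; ",
           "cov_percent is incompatible with the refractory floor")
    }
    if (length(bad) > 0) iv[bad] <- schedule$floor_ms
  }
  starts <- c(0, cumsum(iv))
  starts[starts < dur_ms]
}
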