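#' Parameterize an action potential shape
#'
#' Phenomenological description of a single cardiomyocyte action potential
#' (AP) as a linear upstroke followed by a family-specific repolarization
#' law. Three families are supported:
#'
#' * `"hill"` -- sigmoidal repolarization `V(t) = 1 / (1 + (t/theta)^h)`
#'   measured from repolarization onset. Its APD at `x` percent
#'   repolarization has the closed form `theta * (x/(100-x))^(1/h)`, so the
#'   triangulation ratio APD50/APD90 equals `9^(-1/h)`: large `h` gives a
#'   square, plateau-dominated AP, `h` near 1 a triangulated one.
#' * `"linear"` -- optional flat plateau, then straight-line decay over
#'   `repol_ms` (APD at `x`% equals `plateau_ms + (x/100) * repol_ms`).
#'   With no plateau this is the canonical "perfect triangle".
#' * `"square"` -- flat plateau followed by a one-sample drop to the trough
#'   (the canonical "perfect square": every APD equals `plateau_ms`).
#'
#' @param family `"hill"`, `"linear"` or `"square"`.
#' @param rise_time_ms Duration of the linear upstroke (ms). May be zero,
#'   in which case the upstroke occupies a single sample.
#' @param plateau_ms Flat-top duration before repolarization onset
#'   (linear and square families).
#' @param theta_ms Hill half-repolarization time (ms): the APD50 measured
#'   from repolarization onset.
#' @param h Hill steepness exponent (dimensionless, > 0).
#' @param repol_ms Total linear-decay duration (linear family).
#' @param diastolic_ms Rest interval at the trough appended after
#'   repolarization completes.
#' @param tail_cut Hill family only: repolarization fraction at which the
#'   slowly decaying tail is truncated to give the template finite support
#'   (default 0.99). APDs up to `100 * tail_cut` percent are unaffected by
#'   the truncation.
#' @return An object of class `ap_shape`.
#' @seealso [generate_ap_template()], [ap_shape_apd()]
#' @export
ap_shape <- function(family = c("hill", "linear", "square"),
                     rise_time_ms = 3,
                     plateau_ms = 0,
                     theta_ms = 200,
                     h = 3,
                     repol_ms = 450,
                     diastolic_ms = 50,
                     tail_cut = 0.99) {
  family <- match.arg(family)
  stopifnot(rise_time_ms >= 0, plateau_ms >= 0, diastolic_ms >= 0)
  if (family == "hill") {
    stopifnot(theta_ms >= 0, h > 0, tail_cut > 0.9, tail_cut < 1)
  }
  if (family == "linear") stopifnot(repol_ms >= 0)
  structure(
    list(family = family, rise_time_ms = rise_time_ms,
         plateau_ms = plateau_ms, theta_ms = theta_ms, h = h,
         repol_ms = repol_ms, diastolic_ms = diastolic_ms,
         tail_cut = tail_cut),
    class = "ap_shape")
}

#' Closed-form APD of a shape family, measured from repolarization onset
#'
#' @param shape An [ap_shape()].
#' @param x Repolarization percentage(s) in (0, 100).
#' @return APD in ms measured from the onset of repolarization (end of
#'   plateau for linear/square, end of upstroke for hill).
#' @export
ap_shape_apd <- function(shape, x) {
  stopifnot(inherits(shape, "ap_shape"), all(x > 0), all(x < 100))
  switch(shape$family,
    hill   = shape$theta_ms * (x / (100 - x))^(1 / shape$h),
    linear = (x / 100) * shape$repol_ms,
    square = rep(0, length(x)))
}

#' Closed-form APD measured from beat start (onset of the upstroke)
#'
#' Adds the upstroke and plateau durations to [ap_shape_apd()], matching
#' the measurement convention of the analysis side (APD from beat start).
#'
#' @inheritParams ap_shape_apd
#' @return APD in ms from the start of the upstroke.
#' @export
ap_shape_apd_from_start <- function(shape, x) {
  pre <- shape$rise_time_ms +
    if (shape$family %in% c("linear", "square")) shape$plateau_ms else 0
  pre + ap_shape_apd(shape, x)
}

# Duration of the repolarization limb (onset of repolarization to trough).
repol_support_ms <- function(shape) {
  switch(shape$family,
    hill   = shape$theta_ms * (shape$tail_cut / (1 - shape$tail_cut))^(1 / shape$h),
    linear = shape$repol_ms,
    square = 0)
}

#' Total duration of one AP waveform in ms (upstroke to end of diastole)
#' @inheritParams ap_shape_apd
#' @export
ap_shape_duration_ms <- function(shape) {
  pre <- if (shape$family %in% c("linear", "square")) shape$plateau_ms else 0
  shape$rise_time_ms + pre + repol_support_ms(shape) + shape$diastolic_ms
}

#' Generate a normalized AP waveform template
#'
#' Samples one beat of the shape on a regular grid: the waveform starts at
#' 0, rises linearly over `rise_time_ms` to exactly 1, repolarizes to 0
#' according to the family law and holds 0 for `diastolic_ms`. For the
#' hill family the slowly decaying tail is truncated where the
#' repolarization fraction reaches `tail_cut` (the residual, at most
#' `1 - tail_cut`, is dropped to 0 in one sample).
#'
#' @param shape An [ap_shape()].
#' @param sampling_rate_hz Sampling rate in Hz (> 0).
#' @return Numeric vector of unitless samples in `[0, 1]`; sample `k`
#'   corresponds to time `(k - 1) / sampling_rate_hz`.
#' @examples
#' tpl <- generate_ap_template(ap_shape("hill", rise_time_ms = 2,
#'                                      theta_ms = 250, h = 2), 2000)
#' range(tpl)
#' @export
generate_ap_template <- function(shape, sampling_rate_hz) {
  stopifnot(inherits(shape, "ap_shape"))
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be positive")
  }
  dt_ms <- 1000 / sampling_rate_hz
  rise <- max(shape$rise_time_ms, dt_ms)    # a zero rise occupies one sample
  plat <- if (shape$family %in% c("linear", "square")) shape$plateau_ms else 0
  onset <- rise + plat                      # repolarization onset
  rep_end <- onset + repol_support_ms(shape)
  total_ms <- rep_end + shape$diastolic_ms
  # two extra samples guarantee the trough is reached on the grid
  n <- max(2L, ceiling(total_ms / dt_ms) + 2L)
  t_ms <- (seq_len(n) - 1) * dt_ms

  # upstroke: 0 at t = 0, exactly 1 at t = rise
  v <- pmin(t_ms / rise, 1)
  # repolarization from onset per family law
  idx <- which(t_ms > onset & t_ms < rep_end)
  if (length(idx)) {
    tr <- t_ms[idx] - onset
    v[idx] <- switch(shape$family,
      hill   = 1 / (1 + (tr / shape$theta_ms)^shape$h),
      linear = 1 - tr / shape$repol_ms,
      square = v[idx])
  }
  v[t_ms >= rep_end & t_ms > onset] <- 0
  # the peak sample (first at or after the end of the upstroke) is exactly 1
  # even when the grid does not land on the upstroke end
  i_peak <- which(t_ms >= rise)[1]
  if (!is.na(i_peak) && i_peak > 1) v[i_peak] <- 1
  v
}
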