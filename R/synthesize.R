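#' Electrode coupling parameters
#'
#' Describes how the underlying tissue action potential appears on one
#' electrode. In `"leap"` mode the electrode carries a scaled copy of the
#' AP train (typical amplitudes 350 uV to 10 mV). In `"fp"` mode it
#' carries a field potential: a sharp biphasic depolarization spike plus a
#' low, slow repolarization wave (typical amplitudes below 350 uV). In
#' `"electroporation"` mode the AP-shaped signal decays exponentially with
#' time constant `decay_tau_s`, reverting to an FP-scale residual.
#' `"quiescent"` electrodes carry noise only.
#'
#' @param mode One of `"leap"`, `"fp"`, `"electroporation"`, `"quiescent"`.
#' @param amplitude_uV Peak-to-trough electrode amplitude in uV.
#' @param decay_tau_s Exponential amplitude decay constant in seconds
#'   (electroporation mode).
#' @param residual_fp_uV FP-scale residual amplitude left behind after an
#'   electroporation signal has decayed.
#' @export
coupling_params <- function(mode = c("leap", "fp", "electroporation",
                                     "quiescent"),
                            amplitude_uV = 2000,
                            decay_tau_s = 30,
                            residual_fp_uV = 150) {
  mode <- match.arg(mode)
  stopifnot(amplitude_uV >= 0, residual_fp_uV >= 0)
  if (mode == "electroporation") stopifnot(decay_tau_s > 0)
  structure(list(mode = mode, amplitude_uV = amplitude_uV,
                 decay_tau_s = decay_tau_s, residual_fp_uV = residual_fp_uV),
            class = "coupling_params")
}

#' Early afterdepolarization injection parameters
#'
#' EADs are injected as raised-cosine bumps added to the repolarization
#' limb. `onset_fraction` positions the bump in time between the AP peak
#' (0) and the trough (1); the bump height is specified in uV above the
#' local repolarization trend.
#'
#' @param onset_fraction Position within the repolarization interval,
#'   strictly between 0 and 1.
#' @param amplitude_uV Bump height above the local trend (uV).
#' @param width_ms Bump duration (full raised-cosine support, ms).
#' @param probability Per-beat injection probability in `[0, 1]`.
#' @export
ead_injection <- function(onset_fraction = 0.3, amplitude_uV = 0,
                          width_ms = 40, probability = 0) {
  stopifnot(onset_fraction > 0, onset_fraction < 1, amplitude_uV >= 0,
            width_ms > 0, probability >= 0, probability <= 1)
  structure(list(onset_fraction = onset_fraction,
                 amplitude_uV = amplitude_uV, width_ms = width_ms,
                 probability = probability),
            class = "ead_injection")
}

#' Additive noise parameters
#'
#' @param white_sigma_uV Gaussian white-noise standard deviation (uV).
#' @param drift_amp_uV Amplitude of sinusoidal baseline wander (uV).
#' @param drift_period_s Period of the baseline wander (s).
#' @export
noise_params <- function(white_sigma_uV = 10, drift_amp_uV = 0,
                         drift_period_s = 10) {
  stopifnot(white_sigma_uV >= 0, drift_amp_uV >= 0, drift_period_s > 0)
  structure(list(white_sigma_uV = white_sigma_uV,
                 drift_amp_uV = drift_amp_uV,
                 drift_period_s = drift_period_s),
            class = "noise_params")
}

#' Rate dependence of APD (restitution)
#'
#' Steady-state APD90 as a monotone increasing function of beat period:
#' `APD90_ss(BP) = apd90_max_ms - k_ms * exp(-BP / tau_bp_ms)`. Per beat,
#' APD relaxes toward the steady state of the current beat period over
#' `adaptation_beats` beats (95% adaptation), emulating the slow
#' adjustment of repolarization after a rate change while beat period
#' itself follows immediately.
#'
#' @param apd90_max_ms Asymptotic APD90 at very slow rates (ms).
#' @param k_ms Magnitude of rate-dependent shortening (ms, < apd90_max_ms).
#' @param tau_bp_ms Beat-period scale of the restitution curve (ms).
#' @export
restitution_map <- function(apd90_max_ms = 500, k_ms = 250,
                            tau_bp_ms = 1000) {
  stopifnot(apd90_max_ms > 0, k_ms >= 0, k_ms < apd90_max_ms, tau_bp_ms > 0)
  structure(list(apd90_max_ms = apd90_max_ms, k_ms = k_ms,
                 tau_bp_ms = tau_bp_ms),
            class = "restitution_map")
}

restitution_ss <- function(restitution, bp_ms) {
  restitution$apd90_max_ms -
    restitution$k_ms * exp(-bp_ms / restitution$tau_bp_ms)
}

# Per-beat APD90 sequence: immediate BP change, slow APD adaptation.
beat_apd90_sequence <- function(beats_ms, schedule, restitution, base_apd90) {
  n <- length(beats_ms)
  if (is.null(restitution) || n == 0) return(rep(base_apd90, n))
  bp <- diff(beats_ms)
  bp0 <- if (n >= 2) bp[1] else schedule$mean_bp_ms
  bp_prev <- c(bp0, bp)[seq_len(n)]
  alpha <- 1 - exp(-3 / schedule$adaptation_beats)
  out <- numeric(n)
  cur <- restitution_ss(restitution, bp_prev[1])
  for (i in seq_len(n)) {
    ss <- restitution_ss(restitution, bp_prev[i])
    cur <- cur + alpha * (ss - cur)
    out[i] <- cur
  }
  out
}

# Scale a shape so its APD90 (from repolarization onset) hits a target.
scale_shape_to_apd90 <- function(shape, apd90_target) {
  base <- switch(shape$family,
    hill   = ap_shape_apd(shape, 90),
    linear = ap_shape_apd(shape, 90),
    square = shape$plateau_ms)
  if (base <= 0) return(shape)
  f <- apd90_target / base
  s <- shape
  if (shape$family == "hill") s$theta_ms <- shape$theta_ms * f
  if (shape$family == "linear") s$repol_ms <- shape$repol_ms * f
  if (shape$family == "square") s$plateau_ms <- shape$plateau_ms * f
  s
}

raised_cosine <- function(n_samples) {
  if (n_samples < 1) return(numeric(0))
  x <- seq_len(n_samples) / (n_samples + 1)
  0.5 * (1 - cos(2 * pi * x))
}

#' Synthesize one electrode voltage trace with ground truth
#'
#' Builds a voltage trace in uV for a single electrode from an AP shape, a
#' beat schedule and coupling parameters. LEAP-mode traces are scaled AP
#' template trains (peak-to-trough exactly `amplitude_uV` before noise)
#' with optional EAD bumps. FP-mode traces carry, per beat, a biphasic
#' depolarization spike (the band-limited negative derivative of the AP
#' upstroke) and a raised-cosine repolarization wave centered at the
#' midpoint of the APD50..APD90 interval, with width `APD90 - APD50` and
#' height inversely proportional to that width, so triangulated APs
#' produce the broad, low T-waves seen in real field potentials.
#' Electroporation mode multiplies the LEAP train by
#' `exp(-(t + start_time_s) / decay_tau_s)` and adds an FP-scale residual.
#'
#' @param shape An [ap_shape()].
#' @param schedule A [beat_schedule()].
#' @param coupling A [coupling_params()].
#' @param eads An [ead_injection()] or `NULL`.
#' @param noise A [noise_params()] or `NULL` for a noiseless trace.
#' @param restitution A [restitution_map()] or `NULL` for rate-independent
#'   morphology.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param duration_s Trace duration (s).
#' @param start_time_s Absolute start time of the trace (s); relevant for
#'   electroporation decay across checkpoint recordings.
#' @param seed Optional integer seed making the trace reproducible.
#' @return A list with `trace` (numeric, uV), `t_s` (sample times), and
#'   `beats`, a per-beat ground-truth data frame with columns
#'   `beat_index`, `beat_start_ms`, `true_apd30_ms`, `true_apd50_ms`,
#'   `true_apd90_ms`, `true_rise_ms`, `true_fpd_ms`, `ead_flag`,
#'   `amplitude_uV`.
#' @export
synthesize_electrode_trace <- function(shape, schedule, coupling,
                                       eads = NULL, noise = noise_params(),
                                       restitution = NULL,
                                       sampling_rate_hz = 12500,
                                       duration_s, start_time_s = 0,
                                       seed = NULL) {
  stopifnot(inherits(shape, "ap_shape"), inherits(schedule, "beat_schedule"),
            inherits(coupling, "coupling_params"), duration_s > 0,
            sampling_rate_hz > 0)
  if (!is.null(seed)) set.seed(seed)
  fs <- sampling_rate_hz
  dt_ms <- 1000 / fs
  n <- round(duration_s * fs)
  t_s <- start_time_s + (seq_len(n) - 1) / fs

  empty_truth <- data.frame(beat_index = integer(0), beat_start_ms = numeric(0),
                            true_apd30_ms = numeric(0), true_apd50_ms = numeric(0),
                            true_apd90_ms = numeric(0), true_rise_ms = numeric(0),
                            true_fpd_ms = numeric(0), ead_flag = logical(0),
                            amplitude_uV = numeric(0))

  add_noise <- function(v) {
    if (is.null(noise)) return(v)
    if (noise$white_sigma_uV > 0) {
      v <- v + stats::rnorm(n, 0, noise$white_sigma_uV)
    }
    if (noise$drift_amp_uV > 0) {
      v <- v + noise$drift_amp_uV * sin(2 * pi * t_s / noise$drift_period_s)
    }
    v
  }

  if (coupling$mode == "quiescent") {
    return(list(trace = add_noise(numeric(n)), t_s = t_s,
                beats = empty_truth))
  }

  beats_ms <- generate_beat_times(schedule, duration_s)
  if (length(beats_ms) == 0) {
    return(list(trace = add_noise(numeric(n)), t_s = t_s,
                beats = empty_truth))
  }
  if (ap_shape_duration_ms(shape) > duration_s * 1000) {
    stop("duration_s is shorter than a single beat waveform")
  }

  base_apd90 <- switch(shape$family,
    square = shape$plateau_ms, ap_shape_apd(shape, 90))
  apd90_seq <- beat_apd90_sequence(beats_ms, schedule, restitution, base_apd90)

  nb <- length(beats_ms)
  shapes <- vector("list", nb)
  same_shape <- is.null(restitution)
  tpl0 <- generate_ap_template(shape, fs)
  warned <- FALSE

  unit <- numeric(n)
  truth <- data.frame(beat_index = seq_len(nb), beat_start_ms = beats_ms,
                      true_apd30_ms = NA_real_, true_apd50_ms = NA_real_,
                      true_apd90_ms = NA_real_, true_rise_ms = NA_real_,
                      true_fpd_ms = NA_real_, ead_flag = FALSE,
                      amplitude_uV = NA_real_)
  for (i in seq_len(nb)) {
    sh <- if (same_shape) shape else
      scale_shape_to_apd90(shape, apd90_seq[i])
    shapes[[i]] <- sh
    tpl <- if (same_shape) tpl0 else generate_ap_template(sh, fs)
    i0 <- round(beats_ms[i] / dt_ms) + 1L
    i1 <- i0 + length(tpl) - 1L
    lim <- if (i < nb) round(beats_ms[i + 1] / dt_ms) else n
    if (i1 > lim) {
      if (!warned && i < nb) {
        warning("beat period shorter than waveform duration; ",
                "repolarization truncated")
        warned <- TRUE
      }
      i1 <- lim
    }
    if (i0 > n) next
    len <- i1 - i0 + 1L
    if (len > 0) unit[i0:i1] <- tpl[seq_len(len)]
    truth$true_apd30_ms[i] <- ap_shape_apd_from_start(sh, 30)
    truth$true_apd50_ms[i] <- ap_shape_apd_from_start(sh, 50)
    truth$true_apd90_ms[i] <- ap_shape_apd_from_start(sh, 90)
    truth$true_rise_ms[i] <- max(sh$rise_time_ms, dt_ms)
    truth$true_fpd_ms[i] <- (ap_shape_apd_from_start(sh, 50) +
                             ap_shape_apd_from_start(sh, 90)) / 2
  }

  # amplitude envelope at each sample (and at each beat start for truth)
  env <- switch(coupling$mode,
    leap = rep(coupling$amplitude_uV, n),
    fp = rep(coupling$amplitude_uV, n),
    electroporation = coupling$amplitude_uV * exp(-t_s / coupling$decay_tau_s))
  truth$amplitude_uV <- switch(coupling$mode,
    electroporation = coupling$amplitude_uV *
      exp(-(start_time_s + beats_ms / 1000) / coupling$decay_tau_s),
    rep(coupling$amplitude_uV, nb))

  if (coupling$mode %in% c("leap", "electroporation")) {
    v <- unit * env
    # EAD bumps on the repolarization limb, scaled with the local envelope
    if (!is.null(eads) && eads$probability > 0 && eads$amplitude_uV > 0) {
      hit <- stats::runif(nb) < eads$probability
      wb <- round(eads$width_ms / dt_ms)
      bump <- raised_cosine(wb)
      for (i in which(hit)) {
        sh <- shapes[[i]]
        t_peak <- beats_ms[i] + max(sh$rise_time_ms, dt_ms)
        plat <- if (sh$family %in% c("linear", "square")) sh$plateau_ms else 0
        t_trough <- beats_ms[i] + max(sh$rise_time_ms, dt_ms) + plat +
          repol_support_ms(sh)
        tc <- t_peak + eads$onset_fraction * (t_trough - t_peak)
        j0 <- round((tc - eads$width_ms / 2) / dt_ms) + 1L
        jj <- j0:(j0 + wb - 1L)
        keep <- jj >= 1 & jj <= n
        scale_i <- truth$amplitude_uV[i] / coupling$amplitude_uV
        v[jj[keep]] <- v[jj[keep]] +
          eads$amplitude_uV * scale_i * bump[keep]
        truth$ead_flag[i] <- TRUE
      }
    }
    if (coupling$mode == "electroporation" && coupling$residual_fp_uV > 0) {
      res <- synthesize_fp_train(unit, beats_ms, shapes, shape, fs, n,
                                 coupling$residual_fp_uV)
      v <- v + res
    }
    return(list(trace = add_noise(v), t_s = t_s, beats = truth))
  }

  # fp mode
  v <- synthesize_fp_train(unit, beats_ms, shapes, shape, fs, n,
                           coupling$amplitude_uV)
  list(trace = add_noise(v), t_s = t_s, beats = truth)
}

# Build an FP trace from the unit AP train: per-beat biphasic spike from
# the band-limited negative derivative of the upstroke plus a raised-cosine
# repolarization wave spanning the APD50..APD90 interval.
synthesize_fp_train <- function(unit, beats_ms, shapes, shape, fs, n,
                                amplitude_uV) {
  dt_ms <- 1000 / fs
  nb <- length(beats_ms)
  d <- -c(diff(unit), 0) * fs / 1000          # -dV/dt in 1/ms
  spikes <- numeric(n)
  for (i in seq_len(nb)) {
    sh <- shapes[[i]]
    rise <- max(sh$rise_time_ms, dt_ms)
    j0 <- max(1L, round((beats_ms[i] - 1) / dt_ms) + 1L)
    j1 <- min(n, round((beats_ms[i] + rise + 1) / dt_ms) + 1L)
    spikes[j0:j1] <- d[j0:j1]
  }
  # reference spike size (one-sided) for setting the T-wave height
  u_ref <- max(abs(spikes))
  if (u_ref == 0) u_ref <- 1
  twave <- numeric(n)
  for (i in seq_len(nb)) {
    sh <- shapes[[i]]
    t50 <- ap_shape_apd_from_start(sh, 50)
    t90 <- ap_shape_apd_from_start(sh, 90)
    # wave duration tracks the APD50..APD90 interval but is bounded by the
    # repolarization dispersion of the syncytium (~0.5 s), which also keeps
    # it inside the 1 Hz acquisition band
    w <- max(min(t90 - t50, 500), 20)
    # repolarization waves stay well below the spike (as QRS vs T-wave)
    # and broaden/shrink with triangulation; a 5% floor keeps a residual
    # deflection even for strongly triangulated shapes
    height <- u_ref * max(0.05, min(0.30, 0.30 * 150 / w))
    wb <- round(w / dt_ms)
    if (wb < 3) wb <- 3L
    bump <- raised_cosine(wb) * height
    tc <- beats_ms[i] + (t50 + t90) / 2
    j0 <- round((tc - w / 2) / dt_ms) + 1L
    jj <- j0:(j0 + wb - 1L)
    keep <- jj >= 1 & jj <= n
    twave[jj[keep]] <- twave[jj[keep]] + bump[keep]
  }
  v <- spikes + twave
  # apply the FP acquisition band (1-2000 Hz): the hardware bandwidth
  v <- bandpass(v, fs, 1, min(2000, 0.45 * fs))
  # A band-limited spike has no unique "true" amplitude; the parameter is
  # defined as the peak-to-trough an analysis measurement sees, so the
  # scale is calibrated on the analysis-filtered view of the trace.
  va <- bandpass(v, fs, 1, min(2000, 0.45 * fs))
  ptt <- vapply(seq_len(nb), function(i) {
    j <- round(beats_ms[i] / dt_ms) + 1L
    sh <- shapes[[i]]
    rise <- max(sh$rise_time_ms, dt_ms)
    j0 <- max(1L, j - round(10 / dt_ms))
    j1 <- min(n, j + round((rise + 10) / dt_ms))
    max(va[j0:j1]) - min(va[j0:j1])
  }, numeric(1))
  s <- stats::median(ptt)
  if (s > 0) v <- v * (amplitude_uV / s)
  v
}
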