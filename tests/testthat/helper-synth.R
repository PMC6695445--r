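# Shared builders for synthetic fixtures. Everything is generated in code
# at test time; no stored data.

std_hill <- function(theta = 200, h = 3, rise = 3, dia = 50, cut = 0.99) {
  ap_shape("hill", rise_time_ms = rise, theta_ms = theta, h = h,
           diastolic_ms = dia, tail_cut = cut)
}

# one LEAP electrode trace with known morphology
leap_trace <- function(fs = 2000, theta = 200, h = 3, rise = 3,
                       bp = 1000, cov = 1, amp = 2000, dur = 13,
                       noise_sd = 10, eads = NULL, seed = 1) {
  suppressWarnings(synthesize_electrode_trace(
    std_hill(theta, h, rise), beat_schedule("spontaneous", bp, cov),
    coupling_params("leap", amp), eads = eads,
    noise = if (noise_sd > 0) noise_params(noise_sd) else NULL,
    sampling_rate_hz = fs, duration_s = dur, seed = seed))
}

fp_trace <- function(fs = 2000, theta = 200, h = 3, rise = 3,
                     bp = 1000, cov = 1, amp = 200, dur = 13,
                     noise_sd = 1, seed = 2) {
  suppressWarnings(synthesize_electrode_trace(
    std_hill(theta, h, rise), beat_schedule("spontaneous", bp, cov),
    coupling_params("fp", amp),
    noise = if (noise_sd > 0) noise_params(noise_sd) else NULL,
    sampling_rate_hz = fs, duration_s = dur, seed = seed))
}

# single square-plateau LEAP beat (uV) with an optional raised-cosine bump
# injected on the plateau: the flat trend makes the measured prominence
# equal the injected height, so EAD-rule boundary cases are exact
square_beat_with_bump <- function(amp = 1000, bump_uV = 0, fs = 12500,
                                  plateau = 500, at_ms = 250,
                                  width_ms = 40) {
  tpl <- generate_ap_template(
    ap_shape("square", rise_time_ms = 2, plateau_ms = plateau,
             diastolic_ms = 100), fs) * amp
  if (bump_uV > 0) {
    wb <- round(width_ms * fs / 1000)
    x <- seq_len(wb) / (wb + 1)
    b <- bump_uV * 0.5 * (1 - cos(2 * pi * x))
    j0 <- round(at_ms * fs / 1000)
    tpl[j0:(j0 + wb - 1)] <- tpl[j0:(j0 + wb - 1)] + b
  }
  tpl
}

# independent APD oracle: dense linear interpolation of the sampled
# repolarization fraction, never calling compute_apd
oracle_apd <- function(wave, fs, x) {
  i_peak <- which.max(wave)
  v_peak <- wave[i_peak]
  v_trough <- min(wave[i_peak:length(wave)])
  r <- (v_peak - wave) / (v_peak - v_trough)
  t_ms <- (seq_along(wave) - 1) * 1000 / fs
  post <- i_peak:length(wave)
  vapply(x, function(xx) {
    j <- post[which(r[post] >= xx / 100)[1]]
    if (j == i_peak) return(t_ms[j])
    stats::approx(r[c(j - 1, j)], t_ms[c(j - 1, j)], xout = xx / 100)$y
  }, numeric(1))
}

# paired LEAP/FP sweep over hill morphologies; returns measured FPD and
# APDs per condition
hill_coupling_sweep <- function(n_cond, seed, fs = 2000, h_range = c(1, 6),
                                theta_range = c(100, 400)) {
  set.seed(seed)
  th <- runif(n_cond, theta_range[1], theta_range[2])
  hh <- runif(n_cond, h_range[1], h_range[2])
  out <- data.frame(theta = th, h = hh, fpd = NA_real_,
                    apd50 = NA_real_, apd90 = NA_real_)
  for (k in seq_len(n_cond)) {
    u <- (1.3 * 9^(1 / hh[k]))^hh[k]
    cut <- max(0.92, min(0.99, u / (1 + u)))
    sh <- ap_shape("hill", rise_time_ms = 3, theta_ms = th[k], h = hh[k],
                   diastolic_ms = 50, tail_cut = cut)
    bp <- ceiling(ap_shape_duration_ms(sh) + 120)
    sch <- beat_schedule("spontaneous", bp, 0)
    dur <- 6.5 * bp / 1000
    leap <- synthesize_electrode_trace(sh, sch, coupling_params("leap", 2000),
              noise = noise_params(10), sampling_rate_hz = fs,
              duration_s = dur, seed = seed + k)$trace
    fp <- synthesize_electrode_trace(sh, sch, coupling_params("fp", 300),
            noise = noise_params(1), sampling_rate_hz = fs,
            duration_s = dur, seed = 1000 + k)$trace
    wr <- analyze_well(cbind(leap, fp), fs)
    if (!is.null(wr$fp)) out$fpd[k] <- wr$fp$fpd_ms
    out$apd50[k] <- wr$ap$apd50_ms
    out$apd90[k] <- wr$ap$apd90_ms
  }
  out
}

# 24-well recovery plate: per-well hill morphology, one LEAP and one FP
# electrode per well, EADs in the last 6 wells; noise SD 0.5% of each
# electrode's amplitude
recovery_plate_config <- function(fs = 2000, duration_s = 13) {
  wells <- well_labels(24)
  # rows A-D carry increasing squareness; APD90 targets keep the full
  # repolarization tail (tail_cut 0.98) inside the 1 s beat period
  hs <- rep(c(3, 3.5, 4, 5), each = 6)
  apd90s <- c(seq(300, 370, length.out = 6), seq(320, 420, length.out = 6),
              seq(330, 460, length.out = 6), seq(340, 500, length.out = 6))
  thetas <- apd90s / 9^(1 / hs)
  ov <- list()
  for (i in seq_along(wells)) {
    sh <- std_hill(theta = thetas[i], h = hs[i], rise = 3, cut = 0.98)
    ead <- if (i > 18) {
      # sited on the slow late limb (just before APD90) where the local
      # repolarization slope costs little prominence
      ead_injection(onset_fraction = 0.60, amplitude_uV = 200,
                    width_ms = 40, probability = 0.5)
    } else {
      ead_injection(probability = 0)
    }
    ov[[wells[i]]] <- list(shape = sh, eads = ead)
    ov[[paste0(wells[i], "_E2")]] <- list(
      shape = sh, eads = ead_injection(probability = 0),
      coupling = coupling_params("fp", 200), noise = noise_params(1))
  }
  simulation_config(
    n_wells = 24, electrodes_per_well = 2, sampling_rate_hz = fs,
    duration_s = duration_s,
    shape = std_hill(), schedule = beat_schedule("spontaneous", 1000, 1),
    coupling = coupling_params("leap", 2000), noise = noise_params(10),
    overrides = ov)
}

# per-well ground-truth summary from a synthesize_plate truth table;
# duration_ms mirrors the analyzer's partial-beat rule (a final beat whose
# window is shorter than 75% of the beat period is not analyzed)
truth_well_summary <- function(truth, duration_ms = NULL) {
  drop_partial <- function(df) {
    if (is.null(duration_ms) || nrow(df) < 3) return(df)
    bp <- stats::median(diff(df$beat_start_ms))
    df[df$beat_start_ms <= duration_ms - 0.75 * bp, ]
  }
  out <- list()
  for (w in unique(truth$well)) {
    leap <- drop_partial(truth[truth$well == w & truth$class %in%
                    c("leap", "electroporation"), ])
    fp <- drop_partial(truth[truth$well == w & truth$class == "fp", ])
    bp <- diff(leap$beat_start_ms)
    out[[w]] <- data.frame(
      well = w,
      apd30 = mean(leap$true_apd30_ms), apd50 = mean(leap$true_apd50_ms),
      apd90 = mean(leap$true_apd90_ms), rise = mean(leap$true_rise_ms),
      bp = mean(bp), cov = 100 * stats::sd(bp) / mean(bp),
      ead_pct = 100 * mean(leap$ead_flag),
      amp = mean(leap$amplitude_uV),
      fp_amp = if (nrow(fp)) mean(fp$amplitude_uV) else NA_real_,
      fpd = if (nrow(fp)) mean(fp$true_fpd_ms) else NA_real_)
  }
  do.call(rbind, out)
}
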