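#' Analyze all electrodes of one well
#'
#' Classifies every electrode, extracts AP morphology metrics from the
#' best LEAP electrode (largest median beat amplitude) and FP endpoints
#' averaged across the FP-class electrodes. A well with no beats on any
#' electrode is flagged quiescent and carries no morphology metrics.
#'
#' AP metrics are computed on the amplitude-normalized waveform template
#' averaged over `beats_to_average` beats (the per-beat EAD scan runs on
#' the un-normalized beats). FP duration per electrode is the median over
#' its beats; electrodes whose repolarization feature is below the noise
#' floor contribute `NA` ("ND").
#'
#' @param traces Matrix (samples x electrodes) of one well, in uV.
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param config An [analysis_config()].
#' @param well Optional well label carried into the result.
#' @return A list of class `well_result`; see Details for fields.
#' @export
analyze_well <- function(traces, sampling_rate_hz,
                         config = analysis_config(), well = NA_character_) {
  stopifnot(is.matrix(traces))
  if (ncol(traces) == 0) stop("empty well")
  fs <- sampling_rate_hz
  cls <- lapply(seq_len(ncol(traces)), function(j)
    classify_signal(traces[, j], fs, config))
  classes <- vapply(cls, `[[`, character(1), "class")
  quiescent <- all(classes == "QUIESCENT")

  res <- list(well = well, classes = classes,
              chosen_electrode = NA_integer_, quiescent = quiescent,
              n_beats = 0L, ap = NULL, fp = NULL)

  leap_idx <- which(classes == "LEAP")
  if (length(leap_idx)) {
    amps <- vapply(cls, function(x)
      ifelse(x$class == "LEAP", x$amplitude_uV, -Inf), numeric(1))
    best <- which.max(amps)
    res$chosen_electrode <- best
    bc <- cls[[best]]
    beats <- bc$beats
    res$n_beats <- beats$n_beats
    tpl <- segment_normalize_average(bc$filtered, beats,
                                     config$beats_to_average, config)
    # median-filter the averaged template before threshold crossing: it
    # suppresses the residual noise floor (which otherwise biases the
    # trough and the slow APD90 crossing) while leaving monotone
    # repolarization segments untouched
    apd <- compute_apd(med_smooth(tpl$samples, fs, 5), fs, c(30, 50, 90),
                       beat_start_idx = tpl$beat_start_idx)
    rise <- compute_rise_time(tpl$samples, fs, config)
    bp <- compute_bp_cov(beats)
    ead_beats <- 0L
    for (i in seq_len(beats$n_beats)) {
      w <- bc$filtered[beats$win_start[i]:beats$win_end[i]]
      ev <- detect_eads(w, fs, bc$amplitude_uV, config)
      if (nrow(ev) > 0) ead_beats <- ead_beats + 1L
    }
    res$ap <- list(apd30_ms = unname(apd["apd30"]),
                   apd50_ms = unname(apd["apd50"]),
                   apd90_ms = unname(apd["apd90"]),
                   rise_ms = rise,
                   bp_ms = bp$mean_bp_ms, bp_cov_pct = bp$cov_percent,
                   tri_ratio = triangulation_ratio(unname(apd["apd50"]),
                                                   unname(apd["apd90"])),
                   ead_pct = percent_beats_with_eads(beats$n_beats,
                                                     ead_beats),
                   leap_amp_uV = bc$amplitude_uV)
  }

  fp_idx <- which(classes == "FP")
  if (length(fp_idx)) {
    per <- lapply(fp_idx, function(j) {
      x <- cls[[j]]$filtered
      fpb <- effective_band(fs, config$fp_band[1], config$fp_band[2])
      x <- bandpass(traces[, j], fs, fpb["low"], fpb["high"])
      beats <- detect_beats_fp(x, fs, config)
      if (beats$n_beats == 0) return(NULL)
      bp <- compute_bp_cov(beats)
      bp_ms <- if (is.na(bp$mean_bp_ms) && beats$n_beats >= 2) {
        mean(diff(beats$starts_ms))
      } else bp$mean_bp_ms
      amps <- fpds <- numeric(0)
      for (i in seq_len(beats$n_beats)) {
        w <- x[beats$win_start[i]:beats$win_end[i]]
        si <- beats$start_idx[i] - beats$win_start[i] + 1L
        amps <- c(amps, compute_fp_amplitude(w, fs, si))
        if (!is.na(bp_ms)) {
          f <- compute_fpd(w, fs, bp_ms, config, spike_idx = si)
          fpds <- c(fpds, f$fpd_ms)
        }
      }
      fpd <- if (all(is.na(fpds))) NA_real_ else
        stats::median(fpds, na.rm = TRUE)
      list(amp = stats::median(amps), fpd = fpd, bp = bp_ms)
    })
    per <- per[!vapply(per, is.null, logical(1))]
    if (length(per)) {
      amp <- mean(vapply(per, `[[`, numeric(1), "amp"))
      fpds <- vapply(per, `[[`, numeric(1), "fpd")
      bps <- vapply(per, `[[`, numeric(1), "bp")
      fpd <- if (all(is.na(fpds))) NA_real_ else mean(fpds, na.rm = TRUE)
      bp <- if (all(is.na(bps))) NA_real_ else mean(bps, na.rm = TRUE)
      res$fp <- list(fp_amp_uV = amp, fpd_ms = fpd,
                     fpdc_ms = if (is.na(fpd) || is.na(bp)) NA_real_
                               else fridericia_correct(fpd, bp),
                     bp_ms = bp)
    }
  }
  class(res) <- "well_result"
  res
}

#' Analyze every well of a recording into a metrics table
#'
#' @param recording An [mea_recording()].
#' @param config An [analysis_config()].
#' @return Data frame with one row per well and the fixed metric columns
#'   `apd30_ms`, `apd50_ms`, `apd90_ms`, `rise_ms`, `bp_ms`,
#'   `bp_cov_pct`, `tri_ratio`, `ead_pct`, `leap_amp_uV`, `fp_amp_uV`,
#'   `fpd_ms`, `fpdc_ms`, `fp_bp_ms`, plus `well`, `n_leap`, `n_fp`,
#'   `n_quiescent`, `chosen_electrode`, `n_beats`, `quiescent`.
#' @export
analyze_recording <- function(recording, config = analysis_config()) {
  wells <- recording_wells(recording)
  rows <- lapply(wells, function(w) {
    wr <- analyze_well(well_traces(recording, w),
                       recording$sampling_rate_hz, config, well = w)
    well_result_row(wr)
  })
  do.call(rbind, rows)
}

well_result_row <- function(wr) {
  ap <- wr$ap %||% list(apd30_ms = NA_real_, apd50_ms = NA_real_,
                        apd90_ms = NA_real_, rise_ms = NA_real_,
                        bp_ms = NA_real_, bp_cov_pct = NA_real_,
                        tri_ratio = NA_real_, ead_pct = NA_real_,
                        leap_amp_uV = NA_real_)
  fp <- wr$fp %||% list(fp_amp_uV = NA_real_, fpd_ms = NA_real_,
                        fpdc_ms = NA_real_, bp_ms = NA_real_)
  data.frame(well = wr$well,
             n_leap = sum(wr$classes == "LEAP"),
             n_fp = sum(wr$classes == "FP"),
             n_quiescent = sum(wr$classes == "QUIESCENT"),
             chosen_electrode = wr$chosen_electrode,
             quiescent = wr$quiescent, n_beats = wr$n_beats,
             apd30_ms = ap$apd30_ms, apd50_ms = ap$apd50_ms,
             apd90_ms = ap$apd90_ms, rise_ms = ap$rise_ms,
             bp_ms = ap$bp_ms, bp_cov_pct = ap$bp_cov_pct,
             tri_ratio = ap$tri_ratio, ead_pct = ap$ead_pct,
             leap_amp_uV = ap$leap_amp_uV,
             fp_amp_uV = fp$fp_amp_uV, fpd_ms = fp$fpd_ms,
             fpdc_ms = fp$fpdc_ms, fp_bp_ms = fp$bp_ms)
}

#' Fraction of wells retaining a LEAP signal over checkpoints
#'
#' The best LEAP electrode of each well is chosen on the first
#' checkpoint; a well "retains" its signal at a later checkpoint when
#' that same electrode still satisfies the LEAP classification rule.
#'
#' @param recordings List of [mea_recording()]s, one per checkpoint, all
#'   with the same plate layout.
#' @param checkpoints_min Checkpoint times in minutes (default
#'   `c(0, 2, 5, 10, 20)`).
#' @param config An [analysis_config()].
#' @return Data frame with columns `checkpoint_min`, `fraction_leap`,
#'   `n_wells` (wells with a LEAP electrode at the first checkpoint).
#' @export
stability_timecourse <- function(recordings,
                                 checkpoints_min = c(0, 2, 5, 10, 20),
                                 config = analysis_config()) {
  stopifnot(length(recordings) == length(checkpoints_min))
  wells <- recording_wells(recordings[[1]])
  fs <- recordings[[1]]$sampling_rate_hz
  chosen <- vapply(wells, function(w)
    select_best_electrode(well_traces(recordings[[1]], w), fs, config),
    integer(1))
  keep <- wells[!is.na(chosen)]
  chosen <- chosen[!is.na(chosen)]
  if (length(keep) == 0) stop("no well has a LEAP electrode at checkpoint 0")
  frac <- vapply(seq_along(recordings), function(k) {
    rec <- recordings[[k]]
    miss <- setdiff(keep, recording_wells(rec))
    if (length(miss)) {
      stop("checkpoint ", checkpoints_min[k], " min is missing wells: ",
           paste(miss, collapse = ", "))
    }
    ok <- vapply(seq_along(keep), function(i) {
      tr <- well_traces(rec, keep[i])[, chosen[i]]
      classify_signal(tr, rec$sampling_rate_hz, config)$class == "LEAP"
    }, logical(1))
    mean(ok)
  }, numeric(1))
  data.frame(checkpoint_min = checkpoints_min, fraction_leap = frac,
             n_wells = length(keep))
}

#' Per-group dose-response summary
#'
#' Mean and SD (n-1 denominator) of each metric across the non-quiescent
#' replicate wells of every group, with quiescent wells tallied
#' separately.
#'
#' @param metrics Per-well metrics table from [analyze_recording()].
#' @param pm A [plate_map()] assigning wells to groups.
#' @return Data frame with one row per group x metric: `group`,
#'   `compound`, `dose`, `n`, `n_quiescent`, `metric`, `mean`, `sd`.
#' @export
dose_response_summary <- function(metrics, pm) {
  stopifnot(is.data.frame(metrics), "well" %in% names(metrics))
  df <- merge(metrics, as.data.frame(pm), by = "well")
  if (nrow(df) == 0) stop("no wells shared between metrics and plate map")
  metric_cols <- c("apd30_ms", "apd50_ms", "apd90_ms", "rise_ms", "bp_ms",
                   "bp_cov_pct", "tri_ratio", "ead_pct", "leap_amp_uV",
                   "fp_amp_uV", "fpd_ms", "fpdc_ms")
  metric_cols <- intersect(metric_cols, names(df))
  out <- list()
  for (g in unique(df$group)) {
    sub <- df[df$group == g, ]
    if (nrow(sub) == 0) stop("group with zero wells: ", g)
    live <- sub[!sub$quiescent, ]
    for (m in metric_cols) {
      vals <- live[[m]][!is.na(live[[m]])]
      out[[length(out) + 1L]] <- data.frame(
        group = g, compound = sub$compound[1], dose = sub$dose[1],
        n = nrow(sub), n_quiescent = sum(sub$quiescent), metric = m,
        mean = if (length(vals)) mean(vals) else NA_real_,
        sd = if (length(vals) >= 2) stats::sd(vals) else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Rate-block analysis of a paced recording
#'
#' Stimulus blocks are contiguous runs of (near-)constant stimulus
#' interval. A stimulus is captured when a detected beat start lies
#' within +/- `tolerance_ms` of it. Steady-state beat period and APD90
#' are averaged over the final third of each block, after the slow APD
#' adaptation has settled.
#'
#' @param trace LEAP-class voltage trace (uV).
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param stimulus_times_ms Stimulus train (ms, >= 2 rate blocks are
#'   expected but a single block is analyzed too).
#' @param config An [analysis_config()].
#' @param tolerance_ms Capture window around each stimulus (default 100).
#' @return Data frame with one row per block: `block`, `rate_hz`,
#'   `n_stimuli`, `capture_fraction`, `ss_bp_ms`, `ss_apd90_ms`.
#' @export
pacing_analysis <- function(trace, sampling_rate_hz, stimulus_times_ms,
                            config = analysis_config(),
                            tolerance_ms = 100) {
  stopifnot(length(stimulus_times_ms) >= 2)
  fs <- sampling_rate_hz
  band <- effective_band(fs, config$leap_band[1], config$leap_band[2])
  x <- bandpass(trace, fs, band["low"], band["high"])
  beats <- detect_beats_ap(x, fs, config)
  iv <- diff(stimulus_times_ms)
  blk <- cumsum(c(TRUE, abs(diff(iv)) > 1)) # block id per interval
  blk <- c(blk, blk[length(blk)])           # per stimulus
  out <- list()
  for (b in unique(blk)) {
    st <- stimulus_times_ms[blk == b]
    match_idx <- vapply(st, function(s) {
      d <- abs(beats$starts_ms - s)
      if (length(d) == 0 || min(d) > tolerance_ms) NA_integer_
      else which.min(d)
    }, integer(1))
    cap <- mean(!is.na(match_idx))
    ss <- st[st >= st[1] + 2 / 3 * (st[length(st)] - st[1])]
    ss_idx <- match_idx[stimulus_times_ms[blk == b] %in% ss]
    ss_idx <- ss_idx[!is.na(ss_idx)]
    bp_ss <- if (length(ss_idx) >= 2)
      mean(diff(beats$starts_ms[ss_idx])) else NA_real_
    apd90 <- NA_real_
    if (length(ss_idx) >= 1) {
      vals <- vapply(ss_idx, function(i) {
        w <- x[beats$win_start[i]:beats$win_end[i]]
        unname(compute_apd(med_smooth(w, fs, config$smooth_ms), fs, 90,
                           beat_start_idx = beats$pre_samples + 1L))
      }, numeric(1))
      if (any(!is.na(vals))) apd90 <- mean(vals, na.rm = TRUE)
    }
    out[[length(out) + 1L]] <- data.frame(
      block = b, rate_hz = 1000 / stats::median(diff(st)),
      n_stimuli = length(st), capture_fraction = cap,
      ss_bp_ms = bp_ss, ss_apd90_ms = apd90)
  }
  do.call(rbind, out)
}

#' Two-sided Mann-Whitney rank-sum comparison
#'
#' Exact when group sizes allow and no ties are present, otherwise the
#' normal approximation with midrank tie handling and continuity
#' correction (the behavior of [stats::wilcox.test()]).
#'
#' @param a,b Numeric vectors, each with at least 3 values.
#' @return Two-sided p-value.
#' @export
group_compare <- function(a, b) {
  if (length(a) < 3 || length(b) < 3) {
    stop("each group needs at least 3 values")
  }
  suppressWarnings(stats::wilcox.test(a, b)$p.value)
}
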