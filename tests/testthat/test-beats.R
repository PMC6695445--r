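test_that("bandpass removes DC, preserves in-band tones at zero phase", {
  fs <- 12500
  t <- seq(0, 4, by = 1 / fs)
  trim <- round(0.5 * fs):round(3.5 * fs)
  # DC offset through the FP band
  y <- bandpass(rep(5, length(t)), fs, 1, 2000)
  expect_lt(max(abs(y[trim])), 0.05)
  # 5 Hz tone: amplitude within 5%, phase shift below one sample
  x <- sin(2 * pi * 5 * t)
  y <- bandpass(x, fs, 1, 2000)
  expect_equal((max(y[trim]) - min(y[trim])) / 2, 1, tolerance = 0.05)
  lag <- which.max(y[trim]) - which.max(x[trim])
  expect_lte(abs(lag), 1)
  # band limiting cannot add variance
  set.seed(1)
  w <- rnorm(fs)
  expect_lt(var(bandpass(w, fs, 1, 2000)), var(w))
  # invalid bands
  expect_error(bandpass(w, fs, 3000, 7000), "Nyquist")
  expect_error(bandpass(w, fs, 100, 50), "Nyquist")
})

test_that("the LEAP rule classifies by SD and beat amplitude", {
  fs <- 2000
  # square train, duty 30%: SD = 0.46 * amplitude
  mk <- function(amp) {
    suppressWarnings(synthesize_electrode_trace(
      ap_shape("square", rise_time_ms = 2, plateau_ms = 300,
               diastolic_ms = 100),
      beat_schedule("spontaneous", 1000, 0), coupling_params("leap", amp),
      noise = NULL, sampling_rate_hz = fs, duration_s = 8))$trace
  }
  big <- classify_signal(mk(500), fs)
  expect_identical(big$class, "LEAP")   # SD ~ 230 > 100, amp 500 > 350
  small <- classify_signal(mk(300), fs)
  expect_identical(small$class, "FP")   # amp 300 fails the 350 uV floor
  expect_gt(small$sd_uV, 100)
  flat <- classify_signal(rep(0, 4 * fs), fs)
  expect_identical(flat$class, "QUIESCENT")
  expect_error(classify_signal(numeric(0), fs), "empty")
})

test_that("classification is monotone in amplitude", {
  fs <- 2000
  res <- leap_trace(fs = fs, amp = 360, noise_sd = 5, dur = 8, seed = 3)
  cls <- vapply(c(1, 2, 5, 10), function(k)
    classify_signal(res$trace * k, fs)$class, character(1))
  first_leap <- match("LEAP", cls)
  expect_false(is.na(first_leap))
  expect_true(all(cls[first_leap:length(cls)] == "LEAP"))
})

test_that("AP beat detection recovers noiseless and paced trains", {
  fs <- 2000
  res <- leap_trace(fs = fs, cov = 0, noise_sd = 0, dur = 10, bp = 1000)
  x <- bandpass(res$trace, fs, 0.01, 0.39 * fs)
  bt <- detect_beats_ap(x, fs)
  expect_equal(bt$n_beats, 10L)
  expect_true(all(abs(diff(bt$starts_ms) - 1000) <= 1000 / fs))
  # paced at 2 Hz
  st <- seq(0, 9500, by = 500)
  resp <- suppressWarnings(synthesize_electrode_trace(
    std_hill(theta = 120, h = 4, dia = 20),
    beat_schedule("paced", stimulus_times_ms = st),
    coupling_params("leap", 2000), noise = NULL,
    sampling_rate_hz = fs, duration_s = 10))
  btp <- detect_beats_ap(bandpass(resp$trace, fs, 0.01, 0.39 * fs), fs)
  expect_true(all(abs(diff(btp$starts_ms) - 500) <= 1000 / fs))
  # quiescent trace
  expect_equal(detect_beats_ap(rep(0, 5 * fs), fs)$n_beats, 0L)
})

test_that("beat-start error stays within 2 ms at 2% noise", {
  fs <- 2000
  res <- leap_trace(fs = fs, cov = 1, noise_sd = 40, amp = 2000,
                    dur = 13, seed = 6)   # noise 2% of amplitude
  cl <- classify_signal(res$trace, fs)
  expect_equal(cl$beats$n_beats,
               sum(res$beats$beat_start_ms <= 13000 - 750))
  err <- cl$beats$starts_ms -
    (res$beats$beat_start_ms[seq_len(cl$beats$n_beats)] +
       res$beats$true_rise_ms[seq_len(cl$beats$n_beats)] / 2)
  expect_lt(max(abs(err)), 2)
})

test_that("noise-only traces yield no beats on nearly all seeds", {
  fs <- 2000
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(10 * fs, 0, 10)
    detect_beats_ap(x, fs)$n_beats + detect_beats_fp(x, fs)$n_beats
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("FP spikes are detected down to low post-decay amplitudes", {
  fs <- 2000
  for (amp in c(200, 100, 50)) {
    res <- fp_trace(fs = fs, amp = amp, noise_sd = 2, dur = 10, cov = 0,
                    seed = amp)
    x <- bandpass(res$trace, fs, 1, 0.39 * fs)
    bt <- detect_beats_fp(x, fs)
    expect_equal(bt$n_beats, 10L, info = paste("amp", amp))
    expect_true(all(abs(diff(bt$starts_ms) - 1000) < 5))
  }
})

test_that("templates are scale invariant, bounded and noise-averaged", {
  fs <- 2000
  res <- leap_trace(fs = fs, cov = 0, noise_sd = 0, dur = 10)
  cl <- classify_signal(res$trace, fs)
  tpl <- segment_normalize_average(cl$filtered, cl$beats)
  expect_equal(tpl$n_beats, 5L)
  expect_equal(range(tpl$samples), c(0, 1))
  expect_lte(length(tpl$samples), stats::median(diff(cl$beats$start_idx)))
  # identical noiseless beats: the average equals a single beat
  one <- segment_normalize_average(cl$filtered, cl$beats, n_beats = 1)
  n <- min(length(one$samples), length(tpl$samples))
  expect_equal(tpl$samples[1:n], one$samples[1:n], tolerance = 1e-10)
  # scaling the input changes nothing
  cl10 <- classify_signal(res$trace * 10, fs)
  tpl10 <- segment_normalize_average(cl10$filtered, cl10$beats)
  n <- min(length(tpl10$samples), length(tpl$samples))
  expect_equal(tpl10$samples[1:n], tpl$samples[1:n], tolerance = 1e-8)

  # averaging 5 noisy beats shrinks the noise by sqrt(5)
  sigma <- 20
  resn <- leap_trace(fs = fs, cov = 0, noise_sd = sigma, dur = 10,
                     seed = 9)
  cln <- classify_signal(resn$trace, fs)
  tpln <- segment_normalize_average(cln$filtered, cln$beats)
  m <- min(length(tpln$samples), length(tpl$samples))
  resid <- tpln$samples[1:m] - tpl$samples[1:m]
  # estimate on the diastolic tail, where the clean template is flat
  tail_idx <- (m - round(0.04 * fs)):m
  expect_equal(sd(resid[tail_idx]), sigma / (2000 * sqrt(5)),
               tolerance = 0.2)
  expect_error(segment_normalize_average(rep(1, 100), list()),
               "beat_train")
})

test_that("best-electrode selection maximizes LEAP amplitude", {
  fs <- 2000
  tr <- sapply(c(500, 2000, 800), function(a)
    leap_trace(fs = fs, amp = a, noise_sd = 5, dur = 8,
               seed = a)$trace)
  expect_equal(select_best_electrode(tr, fs), 2L)
  # no LEAP electrode: absent marker
  trfp <- sapply(c(200, 250), function(a)
    fp_trace(fs = fs, amp = a, dur = 8, seed = a)$trace)
  expect_true(is.na(select_best_electrode(trfp, fs)))
  # exact tie resolves to the lower index
  one <- leap_trace(fs = fs, amp = 1000, noise_sd = 0, dur = 8)$trace
  expect_equal(select_best_electrode(cbind(one, one), fs), 1L)
  expect_error(select_best_electrode(matrix(0, 10, 0), fs), "empty")
})
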