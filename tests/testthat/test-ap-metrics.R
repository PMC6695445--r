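test_that("compute_apd validates its inputs", {
  fs <- 2000
  tpl <- generate_ap_template(std_hill(), fs)
  expect_error(compute_apd(tpl, fs, c(0, 50)), "strictly between")
  expect_error(compute_apd(tpl, fs, 150), "strictly between")
  expect_error(compute_apd(rep(1, 100), fs, 50), "repolarization")
  # repolarization is defined peak-to-trough of the window: truncating
  # the tail redefines the trough upward and shortens the apparent APD
  ip <- which.max(tpl)
  i50 <- ip + which(tpl[ip:length(tpl)] < 0.55)[1]
  expect_lt(compute_apd(tpl[seq_len(i50)], fs, 90),
            compute_apd(tpl, fs, 90))
})

test_that("rise time follows the take-off rule", {
  fs <- 12500
  ramp <- function(rise_ms) {
    generate_ap_template(
      ap_shape("linear", rise_time_ms = rise_ms, plateau_ms = 200,
               repol_ms = 400, diastolic_ms = 50), fs)
  }
  expect_equal(compute_rise_time(ramp(10), fs), 10, tolerance = 0.05)
  # slowing the upstroke by 2x doubles the rise time
  expect_equal(compute_rise_time(ramp(20), fs) /
                 compute_rise_time(ramp(10), fs), 2, tolerance = 0.1)
  # one-sample upstroke resolves within two samples
  expect_lte(compute_rise_time(ramp(0), fs), 2 * 1000 / fs + 1e-9)
  # monotone decay has no upstroke
  expect_error(compute_rise_time(seq(1, 0, length.out = 200), fs),
               "upstroke")
})

test_that("beat-period statistics use sample SD over intervals", {
  s <- compute_bp_cov(c(0, 1000, 2000, 3000))
  expect_equal(s$mean_bp_ms, 1000)
  expect_equal(s$cov_percent, 0)
  s <- compute_bp_cov(c(0, 900, 1900, 3000))  # BPs 900, 1000, 1100
  expect_equal(s$mean_bp_ms, 1000)
  expect_equal(s$cov_percent, 10)
  s <- compute_bp_cov(c(0, 800))
  expect_true(is.na(s$cov_percent))
  expect_match(s$reason, "fewer than 3")
  # irregular (pacemaker-like) variability recovered at n = 500
  bt <- generate_beat_times(beat_schedule("spontaneous", 1000, 39.39),
                            duration_s = 510, seed = 21)
  s <- compute_bp_cov(bt)
  expect_lt(abs(s$cov_percent - 39.39), 3)
})

test_that("triangulation ratio is APD50/APD90 with guarded domain", {
  expect_equal(triangulation_ratio(150, 300), 0.5)
  expect_error(triangulation_ratio(400, 300), "monotonicity")
  expect_error(triangulation_ratio(100, 0))
  expect_true(is.na(triangulation_ratio(NA_real_, 300)))
})

test_that("the two-threshold EAD rule is exact at its boundaries", {
  fs <- 12500
  # flat plateau carrier: measured prominence equals the injected height
  expect_equal(nrow(detect_eads(square_beat_with_bump(1000, 30), fs, 1000)),
               1)
  expect_equal(nrow(detect_eads(square_beat_with_bump(1000, 15), fs, 1000)),
               0)  # fails the 20 uV absolute floor
  expect_equal(nrow(detect_eads(square_beat_with_bump(1000, 22), fs, 1000)),
               0)  # fails 2.5% of 1000 uV = 25 uV
  ev <- detect_eads(square_beat_with_bump(1000, 60), fs, 1000)
  expect_equal(ev$prominence_uV, 60, tolerance = 0.005)
  expect_equal(ev$time_ms, 270, tolerance = 3)  # bump centered at 270 ms
  # no events on a clean beat
  expect_equal(nrow(detect_eads(square_beat_with_bump(1000, 0), fs, 1000)),
               0)
})

test_that("EAD detection separates prominences outside a 20% margin", {
  fs <- 5000
  set.seed(33)
  amps <- exp(runif(200, log(5), log(100)))  # log-uniform 5..100 uV
  thr <- 25                                  # binding: 2.5% of 1000 uV
  detected <- vapply(amps, function(a) {
    nrow(detect_eads(square_beat_with_bump(1000, a, fs = fs), fs, 1000)) > 0
  }, logical(1))
  expect_true(all(detected[amps >= 1.2 * thr]))       # sensitivity 1
  expect_true(all(!detected[amps <= 0.8 * thr]))      # specificity 1
})

test_that("EAD fraction of beats is a plain percentage", {
  expect_equal(percent_beats_with_eads(10, 0), 0)
  expect_equal(percent_beats_with_eads(10, 10), 100)
  expect_equal(percent_beats_with_eads(10, 3), 30)
  expect_error(percent_beats_with_eads(0, 0), "empty")
})

test_that("APD recovery under noise stays at the statistical floor", {
  fs <- 5000
  sigma <- 0.01                       # 1% of normalized amplitude
  set.seed(14)
  for (h in c(2, 4, 8)) {
    sh <- ap_shape("hill", rise_time_ms = 0, theta_ms = 200, h = h,
                   diastolic_ms = 30)
    tpl <- generate_ap_template(sh, fs)
    noisy <- tpl + rnorm(length(tpl), 0, sigma)
    x <- c(30, 50, 90)
    expected <- ap_shape_apd(sh, x)
    got <- unname(compute_apd(leapmea:::med_smooth(noisy, fs, 5), fs, x))
    # tolerance: one sample + 0.1 ms plus the statistical floor for a
    # level crossing under noise: 8 sigma_eff / |slope| covers both the
    # first-crossing jitter and the trough-estimation bias (sigma_eff is
    # the running-median residual noise, 1.25 sigma / sqrt(k))
    slope <- abs(sh$h / sh$theta_ms *
                   (x / (100 - x))^((sh$h - 1) / sh$h) *
                   ((100 - x) / 100)^2)
    tol <- 1000 / fs + 0.1 + 8 * (1.25 * sigma / sqrt(25)) / slope
    expect_true(all(abs(got - expected) <= tol),
                info = sprintf("h=%g: %s vs %s", h,
                               toString(round(got, 2)),
                               toString(round(expected, 2))))
  }
})

test_that("morphology metrics are invariant to uniform scaling", {
  fs <- 2000
  res <- leap_trace(fs = fs, noise_sd = 10, dur = 13, seed = 4)
  w1 <- analyze_well(cbind(res$trace), fs)
  w2 <- analyze_well(cbind(res$trace * 7), fs)
  for (mname in c("apd30_ms", "apd50_ms", "apd90_ms", "rise_ms", "bp_ms",
                  "bp_cov_pct", "tri_ratio", "ead_pct")) {
    expect_equal(w2$ap[[mname]], w1$ap[[mname]], tolerance = 1e-8,
                 info = mname)
  }
  expect_equal(w2$ap$leap_amp_uV / w1$ap$leap_amp_uV, 7, tolerance = 1e-6)
})
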