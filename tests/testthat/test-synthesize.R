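test_that("beat schedules produce the requested timing", {
  # zero variability: metronomic beats
  bt <- generate_beat_times(beat_schedule("spontaneous", 1000, 0), 10)
  expect_equal(bt, seq(0, 9000, by = 1000))
  # pacing passthrough at 2 Hz
  st <- seq(0, 4500, by = 500)
  bt <- generate_beat_times(
    beat_schedule("paced", stimulus_times_ms = st), 5)
  expect_equal(diff(bt), rep(500, 9))
  # sampled CoV approaches the configured value
  bt <- generate_beat_times(beat_schedule("spontaneous", 1000, 8.47),
                            duration_s = 510, seed = 11)
  s <- compute_bp_cov(bt)
  expect_gt(s$n_intervals, 450)
  expect_lt(abs(s$cov_percent - 8.47), 2)
  # infeasible variability is rejected (mean below the refractory floor
  # pushes the rejection rate past 50%)
  expect_error(
    generate_beat_times(beat_schedule("spontaneous", 90, 50), 50,
                        seed = 1),
    "rejection")
  expect_error(beat_schedule("paced", stimulus_times_ms = c(0, 0, 10)),
               "increasing")
})

test_that("noiseless LEAP traces conserve amplitude exactly", {
  res <- leap_trace(noise_sd = 0, cov = 0, dur = 5)
  expect_equal(max(res$trace) - min(res$trace), 2000)
  expect_equal(min(res$trace), 0)
})

test_that("electroporation amplitude decays on the configured exponential", {
  fs <- 2000
  sh <- std_hill()
  sch <- beat_schedule("spontaneous", 1000, 0)
  res <- synthesize_electrode_trace(
    sh, sch, coupling_params("electroporation", 2000, decay_tau_s = 30,
                             residual_fp_uV = 0),
    noise = NULL, sampling_rate_hz = fs, duration_s = 5,
    start_time_s = 120)
  # closed form: 2000 * exp(-4) at t = 120 s, below the FP scale
  expect_equal(res$beats$amplitude_uV[1], 2000 * exp(-4), tolerance = 1e-6)
  expect_lt(max(res$trace) - min(res$trace), 50)
  # same electrode at t = 0 is still LEAP scale
  res0 <- synthesize_electrode_trace(
    sh, sch, coupling_params("electroporation", 2000, decay_tau_s = 30),
    noise = NULL, sampling_rate_hz = fs, duration_s = 5)
  expect_gt(max(res0$trace) - min(res0$trace), 1500)
})

test_that("overlapping beats truncate repolarization with a warning", {
  sh <- std_hill(theta = 300, h = 3)   # support ~1.4 s
  expect_warning(
    synthesize_electrode_trace(sh, beat_schedule("spontaneous", 700, 0),
                               coupling_params("leap", 1000), noise = NULL,
                               sampling_rate_hz = 2000, duration_s = 5),
    "truncated")
})

test_that("plate synthesis is deterministic and correctly shaped", {
  cfg <- simulation_config(n_wells = 2, electrodes_per_well = 8,
                           sampling_rate_hz = 12500, duration_s = 30,
                           noise = noise_params(10))
  p1 <- suppressWarnings(synthesize_plate(cfg, seed = 3))
  expect_equal(dim(p1$recording$data), c(375000L, 16L))
  expect_identical(colnames(p1$recording$data)[1], "WA1_E1")
  p2 <- suppressWarnings(synthesize_plate(cfg, seed = 3))
  expect_identical(p1$recording$data, p2$recording$data)
  expect_identical(p1$truth, p2$truth)
  p3 <- suppressWarnings(synthesize_plate(cfg, seed = 4))
  expect_false(identical(p1$recording$data, p3$recording$data))
})

test_that("an all-quiescent plate yields no beats anywhere", {
  cfg <- simulation_config(n_wells = 4, electrodes_per_well = 2,
                           sampling_rate_hz = 2000, duration_s = 6,
                           coupling = coupling_params("quiescent"),
                           noise = noise_params(10))
  pl <- synthesize_plate(cfg, seed = 5)
  expect_equal(nrow(pl$truth), 0)
  met <- analyze_recording(pl$recording)
  expect_true(all(met$quiescent))
  expect_true(all(met$n_beats == 0))
})

test_that("simulation configs round-trip through YAML", {
  cfg <- recovery_plate_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_simulation_config(cfg, path)
  cfg2 <- read_simulation_config(path)
  expect_equal(cfg2, cfg, tolerance = 1e-12)
  # and the regenerated plate matches to serialization precision
  p1 <- suppressWarnings(synthesize_plate(cfg, seed = 9))
  p2 <- suppressWarnings(synthesize_plate(cfg2, seed = 9))
  expect_equal(p1$recording$data, p2$recording$data, tolerance = 1e-9)
})
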