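make_rec <- function(n = 12500, fs = 12500, ids = c("WA1_E1", "WA1_E2")) {
  set.seed(42)
  m <- matrix(rnorm(n * length(ids), 0, 50), ncol = length(ids),
              dimnames = list(NULL, ids))
  mea_recording(m, fs)
}

test_that("recordings round-trip losslessly through CSV + sidecar", {
  rec <- make_rec()
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  rec2 <- read_recording(path)
  expect_equal(rec2$sampling_rate_hz, rec$sampling_rate_hz)
  expect_equal(rec2$start_time_s, rec$start_time_s)
  expect_equal(unname(rec2$data), unname(rec$data), tolerance = 1e-12)
  expect_identical(colnames(rec2$data), colnames(rec$data))
})

test_that("malformed recordings are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,WA1_E1,WA1_E2", "0,1.5,2.5", "0.1,3.5,"), path)
  jsonlite::write_json(list(sampling_rate_hz = 10), sub("csv$", "json", path),
                       auto_unbox = TRUE)
  expect_error(read_recording(path), "WA1_E2")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("time_s", empty)
  jsonlite::write_json(list(sampling_rate_hz = 10), sub("csv$", "json", empty),
                       auto_unbox = TRUE)
  expect_error(read_recording(empty), "no electrodes")

  orphan <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,WA1_E1", "0,1"), orphan)
  expect_error(read_recording(orphan), "sidecar")

  expect_error(read_recording(withr::local_tempfile(fileext = ".csv")),
               "no such file")
  expect_error(mea_recording(matrix(0, 2, 1,
                                    dimnames = list(NULL, "bogus")), 100),
               "malformed")
})

test_that("plate validation reports orphans, empty wells and duplicates", {
  rec <- make_rec(n = 100, fs = 1000,
                  ids = c("WA1_E1", "WA1_E2", "WA2_E1"))
  pm <- plate_map(data.frame(well = c("A1", "A2"), group = "vehicle"))
  expect_length(validate_plate(rec, pm), 0)

  pm2 <- plate_map(data.frame(well = "A1", group = "vehicle"))
  expect_length(validate_plate(rec, pm2), 1)   # A2 electrodes unmapped

  pm3 <- plate_map(data.frame(well = c("A1", "A2", "B1"),
                              group = "vehicle"))
  expect_length(validate_plate(rec, pm3), 1)   # B1 has no electrodes

  bad <- rec
  colnames(bad$data) <- c("WA1_E1", "WA1_E1", "WA2_E1")
  expect_length(validate_plate(bad, pm), 1)    # duplicate ID
})

test_that("plate maps round-trip and enforce their invariants", {
  pm <- plate_map(data.frame(well = c("A1", "A2"), group = c("drug", "veh"),
                             compound = "E-4031", dose = c(10, 0),
                             dose_units = "nM"))
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_plate_map(pm, path)
    pm2 <- read_plate_map(path)
    expect_equal(pm2$well, pm$well)
    expect_equal(pm2$dose, pm$dose, tolerance = 1e-12)
  }
  expect_error(plate_map(data.frame(well = c("A1", "A1"), group = "g")),
               "duplicate")
  expect_error(plate_map(data.frame(well = "A1", group = "")), "empty")
})

test_that("well accessors slice recordings by electrode grammar", {
  rec <- make_rec(n = 100, fs = 1000,
                  ids = c("WA1_E2", "WA1_E1", "WB3_E1"))
  expect_equal(recording_wells(rec), c("A1", "B3"))
  tr <- well_traces(rec, "A1")
  expect_identical(colnames(tr), c("WA1_E1", "WA1_E2"))  # ordered by index
  expect_error(well_traces(rec, "C1"), "no electrodes")
})
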