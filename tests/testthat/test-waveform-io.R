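test_that("waveform write/read round trip preserves data and metadata", {
  set.seed(1)
  rec <- pressure_recording(round(rnorm(1000, 60, 20), 5), 500,
                            start_time = "2024-03-01T08:30:00Z")
  rec$samples[c(10, 500)] <- NA
  rec$gap_mask[c(10, 500)] <- TRUE
  f <- tempfile(fileext = ".txt")
  write_recording(rec, f)
  back <- read_recording(f)
  expect_equal(back$sampling_rate_hz, 500)
  expect_equal(back$start_time, "2024-03-01T08:30:00Z")
  expect_equal(back$units, "mmHg")
  expect_identical(which(back$gap_mask), c(10L, 500L))
  expect_equal(back$samples, rec$samples, tolerance = 1e-9)

  # serialize-parse-serialize is a fixed point on the text form
  f2 <- tempfile(fileext = ".txt")
  write_recording(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("a 1000-sample file at 500 Hz spans 2 seconds", {
  rec <- pressure_recording(rep(50, 1000), 500)
  f <- tempfile()
  write_recording(rec, f)
  back <- read_recording(f)
  expect_length(back$samples, 1000L)
  expect_equal(rec_duration(back), 2)
})

test_that("parse errors name the offending line and field", {
  f <- tempfile()
  writeLines(c("# sampling_rate_hz: 500", "# units: mmHg",
               "# start_time: 2024-01-01T00:00:00Z",
               "1.0", "2.0", "oops", "4.0"), f)
  expect_error(read_recording(f), "line 6")

  writeLines(c("# units: mmHg", "# start_time: x", "1.0"), f)
  expect_error(read_recording(f), "sampling_rate_hz")

  writeLines(c("# sampling_rate_hz: -5", "# units: mmHg",
               "# start_time: x", "1.0"), f)
  expect_error(read_recording(f), "nonpositive")
})

test_that("metrics tables round-trip CSV beyond 6 significant digits", {
  cfg <- sim_config(duration_s = 20, rr_cv = 0, noise_sd_mmHg = 0,
                    drift_amplitude_mmHg = 0)
  an <- quiet_analyze(simulate_recording(cfg)$recording)
  f <- tempfile(fileext = ".csv")
  write_metrics_table(an$beats, f)
  lines <- readLines(f)
  expect_length(lines, nrow(an$beats) + 1L)  # 80 beats -> 80 rows + header
  back <- read_metrics_table(f)
  expect_equal(back$tau66_ms, an$beats$tau66_ms, tolerance = 1e-7)
  expect_equal(back$lvsp_mmHg, an$beats$lvsp_mmHg, tolerance = 1e-7)
})

test_that("write_metrics_table rejects empty or non-tabular input", {
  expect_error(write_metrics_table(data.frame(), tempfile()), "empty")
  expect_error(write_metrics_table(list(1, "a"), tempfile()), "data.frame")
  bad <- data.frame(x = 1)
  bad$y <- list(1)
  expect_error(write_metrics_table(bad, tempfile()), "atomic")
})

test_that("calibration fits affine devices to machine precision", {
  # identity device
  id <- fit_calibration(calibration_record(c(750, 850, 950), c(750, 850, 950)))
  expect_equal(id$slope, 1, tolerance = 1e-12)
  expect_equal(id$intercept, 0, tolerance = 1e-9)
  expect_equal(max(abs(id$residuals)), 0, tolerance = 1e-9)

  # f = 2p + 10 inverts to slope 0.5, intercept -5
  map <- fit_calibration(calibration_record(c(750, 850, 950),
                                            2 * c(750, 850, 950) + 10))
  expect_equal(map$slope, 0.5, tolerance = 1e-12)
  expect_equal(map$intercept, -5, tolerance = 1e-9)

  # brute-force grid least-squares oracle around the analytic optimum
  sse <- function(s, b) sum((c(750, 850, 950) - (s * (2 * c(750, 850, 950) + 10) + b))^2)
  grid <- expand.grid(s = seq(0.48, 0.52, by = 0.001),
                      b = seq(-7, -3, by = 0.1))
  best <- grid[which.min(mapply(sse, grid$s, grid$b)), ]
  expect_equal(map$slope, best$s, tolerance = 1e-9)
  expect_equal(map$intercept, best$b, tolerance = 1e-9)
})

test_that("calibration rejects degenerate inputs", {
  expect_error(calibration_record(c(850, 850), c(1, 2)), "insufficient|increasing")
  expect_error(calibration_record(850, 1), "insufficient")
  expect_error(fit_calibration(calibration_record(c(750, 850), c(5, 5))),
               "degenerate")
})

test_that("three collinear points leave zero residuals", {
  map <- fit_calibration(calibration_record(c(750, 850, 950),
                                            c(1000, 1200, 1400)))
  expect_equal(map$residuals, rep(0, 3), tolerance = 1e-9)
})

test_that("apply_calibration subtracts ambient pressure per sample", {
  id <- fit_calibration(calibration_record(c(750, 950), c(750, 950)))
  raw <- pressure_recording(c(870, 880), 500, units = "raw_freq")
  g <- apply_calibration(raw, id, ambient = 760)
  expect_equal(g$samples, c(110, 120))
  expect_equal(g$units, "mmHg")
  # ambient 0 leaves the pure affine map
  g0 <- apply_calibration(raw, id, ambient = 0)
  expect_equal(g0$samples, c(870, 880))
  expect_error(apply_calibration(raw, id, ambient = c(1, 2, 3)), "ambient")
})

test_that("an ambient recording is resampled onto the signal time base", {
  id <- fit_calibration(calibration_record(c(750, 950), c(750, 950)))
  raw <- pressure_recording(rep(870, 500), 500, start_time = "2024-01-01T00:00:00Z",
                            units = "raw_freq")
  # ambient sampled at 1 Hz, ramping 760 -> 761 over the same second
  amb <- pressure_recording(c(760, 761), 1, start_time = "2024-01-01T00:00:00Z")
  g <- apply_calibration(raw, id, ambient = amb)
  expect_equal(g$samples[1], 110, tolerance = 1e-9)
  expect_equal(g$samples[500], 870 - 760.998, tolerance = 1e-9)
})

test_that("simulated absolute pressures calibrate back to gauge output", {
  sim <- simulate_recording(sim_config(duration_s = 5, seed = 3))
  slope_dev <- 2.5
  icpt_dev <- 40
  raw <- pressure_recording(((sim$recording$samples + 760) - icpt_dev) / slope_dev * slope_dev + 0,
                            500, units = "raw_freq")
  raw$samples <- ((sim$recording$samples + 760) - icpt_dev) / slope_dev
  pts <- c(750, 850, 950)
  map <- fit_calibration(calibration_record(pts, (pts - icpt_dev) / slope_dev))
  g <- apply_calibration(raw, map, ambient = 760)
  expect_equal(g$samples, sim$recording$samples, tolerance = 1e-9)
})
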