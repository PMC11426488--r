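test_that("config defaults carry the published analysis constants", {
  cfg <- analysis_config()
  expect_equal(cfg$tau_rise, 0.02)
  expect_equal(cfg$tau_decay, 10)
  expect_equal(cfg$lp_sensor_cutoff, 5)
  expect_equal(cfg$lp_accel_cutoff, 20)
  expect_equal(c(cfg$band_lo, cfg$band_hi), c(5, 14))
  expect_equal(cfg$min_event_separation, 5)
  expect_equal(cfg$min_source_distance, 15)
  expect_equal(cfg$likelihood_min, 0.9)
  expect_equal(cfg$window_half, 5)
  expect_equal(cfg$bin_width, 1)
  expect_equal(cfg$random_exclusion, 1)
  expect_equal(cfg$head_median_window, 1)
  expect_equal(cfg$angle_mean_window, 3)
})

test_that("an empty config file yields the defaults; set fields echo back", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(character(0), f)
  cfg <- load_config(f)
  expect_equal(cfg$tau_rise, 0.02)
  expect_equal(cfg$tau_decay, 10)

  writeLines(c("band_lo: 5", "band_hi: 14"), f)
  cfg2 <- load_config(f)
  expect_equal(cfg2$band_lo, 5)
  expect_equal(cfg2$band_hi, 14)
})

test_that("config validation rejects inconsistent settings by field name", {
  expect_error(analysis_config(band_lo = 14, band_hi = 5), "band_lo")
  expect_error(analysis_config(lp_sensor_cutoff = 60), "lp_sensor_cutoff")
  expect_error(analysis_config(likelihood_min = 1.5), "likelihood_min")
  expect_error(analysis_config(tau_rise = 11), "tau_rise")
  expect_error(analysis_config(slope_window = 0), "slope_window")
  expect_error(analysis_config(not_a_field = 1), "not_a_field")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("band_lo: 14\nband_hi: 5", f)
  expect_error(load_config(f), "band_lo")
})

test_that("config round-trips through YAML field-for-field", {
  cfg <- analysis_config(fs_sensor = 250, event_ratio_threshold = 2.2,
                         rng_seed = 77L)
  f <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, f)
  cfg2 <- load_config(f)
  expect_equal(unclass(cfg2), unclass(cfg))
})

test_that("time-series CSVs round-trip exactly and reject bad time axes", {
  set.seed(1)
  ts <- time_series(rnorm(100), fs = 100, t0 = 2.5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_timeseries_csv(ts, f)
  back <- read_timeseries_csv(f)
  expect_lt(max(abs(back$values - ts$values)), 1e-9)
  expect_equal(back$fs, ts$fs, tolerance = 1e-9)
  expect_equal(back$t0, ts$t0, tolerance = 1e-9)

  acc <- time_series(matrix(rnorm(300), ncol = 3), fs = 100,
                     channels = c("x", "y", "z"))
  write_timeseries_csv(acc, f)
  back3 <- read_timeseries_csv(f)
  expect_equal(ncol(back3$values), 3L)
  expect_lt(max(abs(back3$values - acc$values)), 1e-9)

  # a 2x gap in t must be rejected as non-uniform
  df <- data.frame(t = c(0, 0.01, 0.02, 0.04, 0.05), value = 1:5)
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_timeseries_csv(f), "uniform")
})

test_that("keypoint CSV reader handles the 3-row pose-estimator dialect", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scorer,net,net,net,net,net,net,net,net,net",
    paste0("bodyparts,", paste(rep(c("nose", "neck", "body"), each = 3),
                               collapse = ",")),
    paste0("coords,", paste(rep(c("x", "y", "likelihood"), 3),
                            collapse = ",")),
    "0,10,20,0.95,11,21,1,12,22,1",
    "1,10.5,20.5,1,11.5,21.5,1,12.5,22.5,1",
    "2,11,21,1,12,22,0.8,13,23,1"), f)
  tr <- read_keypoint_csv(f, fps = 30)
  expect_equal(nrow(tr$frames), 3L)
  expect_equal(tr$frames$nose_p[1], 0.95)   # likelihood passthrough
  expect_equal(tr$frames$neck_p[3], 0.8)
  expect_equal(tr$frames$body_x[2], 12.5)

  # missing bodypart columns must be named in the error
  writeLines(c(
    "scorer,net,net,net,net,net,net",
    paste0("bodyparts,", paste(rep(c("nose", "body"), each = 3),
                               collapse = ",")),
    paste0("coords,", paste(rep(c("x", "y", "likelihood"), 2),
                            collapse = ",")),
    "0,1,2,1,3,4,1"), f)
  expect_error(read_keypoint_csv(f, fps = 30), "neck")

  # non-numeric cell
  writeLines(c(
    "scorer,net,net,net,net,net,net,net,net,net",
    paste0("bodyparts,", paste(rep(c("nose", "neck", "body"), each = 3),
                               collapse = ",")),
    paste0("coords,", paste(rep(c("x", "y", "likelihood"), 3),
                            collapse = ",")),
    "0,oops,20,1,11,21,1,12,22,1"), f)
  expect_error(read_keypoint_csv(f, fps = 30), "non-numeric")
})

test_that("keypoint CSV writer and reader are inverse", {
  set.seed(2)
  n <- 5L
  tr <- make_track(matrix(runif(2 * n, 0, 100), ncol = 2),
                   matrix(runif(2 * n, 0, 100), ncol = 2),
                   matrix(runif(2 * n, 0, 100), ncol = 2),
                   p = c(1, 1, 0.5, 1, 0.95))
  f <- withr::local_tempfile(fileext = ".csv")
  write_keypoint_csv(tr, f)
  back <- read_keypoint_csv(f, fps = 30)
  expect_equal(back$frames, tr$frames, tolerance = 1e-12)
})

test_that("events CSV round-trips retained flags and reasons", {
  ev <- plumekin:::new_plume_events(
    onset_s = c(10, 12, 20), ratio = c(2.1, 1.9, 2.5),
    distance_px = c(40, 30, 10),
    retained = c(TRUE, FALSE, FALSE),
    reason = c("", "separation", "proximity"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(ev, f)
  back <- read_events_csv(f)
  expect_equal(back$onset_s, ev$onset_s)
  expect_equal(back$retained, ev$retained)
  expect_equal(back$reason, ev$reason)
})

test_that("trial records enforce geometry and overlap invariants", {
  sens <- time_series(rnorm(100), 100)
  acc <- time_series(matrix(rnorm(300), ncol = 3), 100)
  trk <- make_track(matrix(1, 30, 2), matrix(2, 30, 2), matrix(3, 30, 2))
  expect_error(trial_record("t", sens, acc, trk, port_xy = c(900, 50),
                            arena_bounds = c(0, 0, 800, 800),
                            in_arena = c(0, 1)), "port_xy")
  expect_error(trial_record("t", sens, acc, trk, port_xy = c(400, 400),
                            arena_bounds = c(0, 0, 800, 800),
                            in_arena = c(50, 60)), "overlap")
  tr <- trial_record("t", sens, acc, trk, port_xy = c(400, 400),
                     arena_bounds = c(0, 0, 800, 800), in_arena = c(0, 1))
  expect_s3_class(tr, "trial_record")
})
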