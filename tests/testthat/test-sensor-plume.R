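cfg <- analysis_config()

test_that("low-pass filter has unit DC gain and the right roll-off", {
  fs <- 100
  t <- seq(0, 10, by = 1 / fs)
  const <- lowpass(time_series(rep(3.7, length(t)), fs), 5)
  expect_lt(max(abs(const$values - 3.7)), 1e-9)

  interior <- seq(2 * fs, 8 * fs)
  slow <- lowpass(time_series(sin(2 * pi * 1 * t), fs), 5)
  expect_gt(max(abs(slow$values[interior, 1])), 0.99)   # 1 Hz preserved

  fast <- lowpass(time_series(sin(2 * pi * 20 * t), fs), 5)
  expect_lt(max(abs(fast$values[interior, 1])), 0.1)    # 20 Hz crushed
})

test_that("deconvolving the kernel itself returns a near-impulse", {
  fs <- 100
  k <- doe_kernel(6000, fs, 0.02, 10)
  d <- deconvolve(time_series(k, fs))$values[, 1]
  expect_gt(sum(d[1:3]) / sum(abs(d)), 0.95)
  expect_error(deconvolve(time_series(k, fs), tau_rise = 10,
                          tau_decay = 0.02), "tau")
})

test_that("an impulse train is recovered with exact times, 5% amplitudes", {
  fs <- 100
  n <- 6000
  x <- numeric(n)
  at <- c(1001L, 2501L, 4001L)
  x[at] <- fs   # three unit-mass impulses
  y <- convolve_kernel(time_series(x, fs))
  d <- deconvolve(y)$values[, 1]
  # peaks exactly at the impulse samples
  for (i in at) expect_equal(which.max(d[(i - 10):(i + 10)]), 11L)
  expect_lt(max(abs(d[at] / fs - 1)), 0.05)
})

test_that("convolve-deconvolve round trip is tight on noiseless traces", {
  fs <- 100
  set.seed(11)
  x <- numeric(3000)
  x[c(500, 1400, 2200)] <- fs
  y <- convolve_kernel(time_series(x, fs))
  rt <- convolve_kernel(deconvolve(y))
  expect_lt(max(abs(rt$values - y$values)) / diff(range(y$values)), 1e-3)
})

test_that("forward convolution matches the direct time-domain oracle", {
  fs <- 50
  x <- numeric(600)
  x[c(40, 300)] <- c(2, 0.5) * fs
  y <- convolve_kernel(time_series(x, fs))$values[, 1]
  expect_lt(max(abs(y - oracle_convolve(x, fs, k_len = 600))), 1e-8)
})

test_that("slope-ratio detector localizes a step and respects thresholds", {
  fs <- 100
  st <- time_series(c(rep(0, 1000), rep(1, 1000)), fs)
  ev <- detect_events(st, cfg, threshold = 2)
  expect_equal(nrow(ev), 1L)
  expect_gte(ev$onset_s, 10 - 1 / fs)
  expect_lte(ev$onset_s, 10 + 0.25)

  expect_equal(nrow(detect_events(st, cfg, threshold = 1e6)), 0L)
  zero <- time_series(rep(0, 3000), fs)
  expect_equal(nrow(detect_events(zero, cfg)), 0L)
  expect_error(detect_events(time_series(rep(0, 150), fs), cfg), "longer")
})

test_that("vectorized slope ratio agrees with the per-sample OLS oracle", {
  on <- schedule_onsets(30, cfg, seed = 5)
  tr <- gen_sensor_trace(on, cfg, seed = 55, duration = 30)
  dec <- deconvolve(lowpass(tr, cfg$lp_sensor_cutoff),
                    lambda = cfg$deconv_lambda)
  sr <- slope_ratio(dec, cfg)
  orc <- oracle_slope_ratio(dec$values[, 1], dec$fs)
  ok <- !is.na(sr$ratio)
  expect_identical(which(ok), which(!is.na(orc)))
  expect_lt(max(abs(sr$ratio[ok] - orc[ok])), 1e-9)
})

test_that("detection is invariant to a DC offset on the raw trace", {
  on <- schedule_onsets(60, cfg, seed = 9)
  tr <- gen_sensor_trace(on, cfg, seed = 99, duration = 60)
  shifted <- time_series(tr$values + 5, tr$fs)
  pipe <- function(x) {
    detect_events(deconvolve(lowpass(x, cfg$lp_sensor_cutoff),
                             lambda = cfg$deconv_lambda), cfg)$onset_s
  }
  expect_equal(pipe(shifted), pipe(tr), tolerance = 1e-6)
})

test_that("slow drift at 5x noise SD barely changes the detected count", {
  counts <- function(drift) {
    n <- 0L
    for (i in 1:10) {
      on <- schedule_onsets(120, cfg, seed = 200 + i)
      tr <- gen_sensor_trace(on, cfg, seed = 300 + i, drift_amp = drift)
      dec <- deconvolve(lowpass(tr, cfg$lp_sensor_cutoff),
                        lambda = cfg$deconv_lambda)
      n <- n + nrow(detect_events(dec, cfg))
    }
    n
  }
  n_drift <- counts(5 * 2.5e-4)
  n_flat <- counts(0)
  expect_lte(abs(n_drift - n_flat) / n_flat, 0.10)
})

test_that("threshold calibration on blanks meets its targets", {
  blanks <- lapply(1:5, function(i) {
    gen_sensor_trace(numeric(0), cfg, seed = 400 + i, duration = 60)
  })
  # target 0: threshold above every observed ratio, so zero events remain
  cal0 <- calibrate_threshold(blanks, cfg, target_fp_rate = 0)
  expect_gt(cal0$threshold, cal0$max_ratio)
  expect_equal(cal0$rate_at_threshold, 0)

  cal <- calibrate_threshold(blanks, cfg, target_fp_rate = 0.5)
  expect_lte(cal$rate_at_threshold, 0.5)
  expect_lt(cal$threshold, cal0$threshold + 1e-9)

  # a blank that actually contains an event inflates the threshold: warn
  dirty <- c(blanks[1:2],
             list(gen_sensor_trace(30, cfg, seed = 444, duration = 60)))
  expect_warning(calibrate_threshold(dirty, cfg, target_fp_rate = 0.1),
                 "real events")
  expect_error(calibrate_threshold(list(), cfg), "blank")
})

test_that("group-data filters reject by separation, proximity and edge", {
  ev <- plumekin:::new_plume_events(onset_s = c(3, 10, 12, 20, 56),
                                    ratio = rep(2, 5))
  n <- 30 * 60
  far <- make_track(matrix(rep(c(101, 100), each = n), ncol = 2),
                    matrix(rep(c(100, 100), each = n), ncol = 2),
                    matrix(rep(c(99, 100), each = n), ncol = 2))
  out <- filter_events(ev, far, port_xy = c(500, 500), in_arena = c(0, 60),
                       config = cfg)
  expect_equal(out$retained, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$reason, c("edge", "", "separation", "", "edge"))

  # animal parked 10 px from the port: proximity rejection
  near <- make_track(matrix(rep(c(101, 100), each = n), ncol = 2),
                     matrix(rep(c(100, 100), each = n), ncol = 2),
                     matrix(rep(c(99, 100), each = n), ncol = 2))
  out2 <- filter_events(plumekin:::new_plume_events(20, 2), near,
                        port_xy = c(109, 100), in_arena = c(0, 60),
                        config = cfg)
  expect_false(out2$retained)
  expect_equal(out2$reason, "proximity")
  expect_equal(out2$distance_px, 10, tolerance = 1e-9)

  # single clean mid-trial event far from the port is retained
  out3 <- filter_events(plumekin:::new_plume_events(20, 2), far,
                        port_xy = c(500, 500), in_arena = c(0, 60),
                        config = cfg)
  expect_true(out3$retained)
})

test_that("detector recall and precision hold at generator-default SNR", {
  tp <- fp <- nt <- 0L
  for (i in 1:10) {
    on <- schedule_onsets(120, cfg, seed = 500 + i)
    tr <- gen_sensor_trace(on, cfg, seed = 600 + i)
    dec <- deconvolve(lowpass(tr, cfg$lp_sensor_cutoff),
                      lambda = cfg$deconv_lambda)
    m <- match_events(detect_events(dec, cfg)$onset_s, on)
    tp <- tp + m$tp; fp <- fp + m$fp; nt <- nt + length(on)
  }
  expect_gte(tp / nt, 0.9)
  expect_gte(tp / (tp + fp), 0.9)
})
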