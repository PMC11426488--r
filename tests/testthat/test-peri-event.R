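cfg <- analysis_config()

make_events <- function(onsets, retained = rep(TRUE, length(onsets))) {
  plumekin:::new_plume_events(onsets, rep(2, length(onsets)),
                              retained = retained,
                              reason = ifelse(retained, "", "separation"))
}

test_that("real windows re-align the series to each retained onset", {
  fs <- 50
  tt <- seq(0, 60 - 1 / fs, by = 1 / fs)
  ident <- time_series(tt, fs)   # series whose value IS time
  ev <- make_events(c(20, 41.5))
  w <- extract_real_windows(ident, ev, cfg)
  expect_equal(nrow(w$real), 2L)
  expect_equal(w$real[1, ], 20 + w$time_axis, tolerance = 1e-9)
  expect_equal(w$real[2, ], 41.5 + w$time_axis, tolerance = 1e-9)

  # rejected events contribute no rows
  w2 <- extract_real_windows(ident, make_events(c(20, 30, 41.5),
                                                c(TRUE, FALSE, TRUE)), cfg)
  expect_equal(nrow(w2$real), 2L)

  # an event too close to the recording edge is a hard error
  expect_error(extract_real_windows(ident, make_events(3), cfg), "edge")
})

test_that("surrogate onsets match counts and avoid the exclusion zones", {
  fs <- 50
  ident <- time_series(seq(0, 120 - 1 / fs, by = 1 / fs), fs)
  ev <- make_events(c(20, 50, 80))
  sur <- sample_random_windows(ident, ev, c(0, 120), cfg, seed = 5)
  expect_equal(nrow(sur$random), 3L)

  draws <- sample_random_onsets(ev, c(0, 120), cfg, seed = 6, n_draw = 1000)
  expect_length(draws, 1000L)
  for (o in ev$onset_s) expect_true(all(abs(draws - o) >= cfg$random_exclusion))
  expect_true(all(draws >= cfg$window_half & draws <= 120 - cfg$window_half))

  # same seed, same draws
  expect_identical(draws,
                   sample_random_onsets(ev, c(0, 120), cfg, seed = 6,
                                        n_draw = 1000))
  expect_error(sample_random_onsets(ev, c(0, 8), cfg, seed = 1), "short")
})

test_that("surrogate onsets are uniform over the admissible times", {
  ev <- make_events(c(30, 60))
  draws <- sample_random_onsets(ev, c(0, 200), cfg, seed = 8, n_draw = 1e4)
  # map through the admissible-interval CDF and compare to uniform
  adm <- plumekin:::subtract_intervals(matrix(c(5, 195), 1),
                                       cbind(ev$onset_s - 1, ev$onset_s + 1))
  adm <- adm[order(adm[, 1]), , drop = FALSE]
  len <- adm[, 2] - adm[, 1]
  cum <- c(0, cumsum(len))
  u <- vapply(draws, function(d) {
    i <- which(d >= adm[, 1] & d <= adm[, 2])[1]
    (cum[i] + d - adm[i, 1]) / sum(len)
  }, numeric(1))
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
})

test_that("bin means tile the window half-open and handle gaps", {
  fs <- 10
  ident <- time_series(seq(0, 60 - 1 / fs, by = 1 / fs), fs)
  w <- extract_real_windows(ident, make_events(c(20, 30)), cfg)
  w$real[] <- 7
  bm <- bin_means(w, "real", cfg)
  expect_equal(dim(bm), c(2L, 10L))
  expect_true(all(bm == 7))
  expect_equal(colnames(bm)[1], "-5 to -4")

  # identity series: bin means are (almost) the bin midpoints
  w2 <- extract_real_windows(ident, make_events(20), cfg)
  bm2 <- bin_means(w2, "real", cfg) - 20
  mids <- seq(-4.5, 4.5, by = 1)
  expect_equal(as.numeric(bm2), mids, tolerance = 0.06)

  # an all-missing bin is NA
  w3 <- extract_real_windows(ident, make_events(20), cfg)
  w3$real[1, w3$time_axis >= -5 & w3$time_axis < -4] <- NA
  bm3 <- bin_means(w3, "real", cfg)
  expect_true(is.na(bm3[1, 1]))
  expect_false(anyNA(bm3[1, -1]))
})

test_that("per-bin KS behaves at the null, under shifts, and on ties", {
  set.seed(31)
  mk <- function(v) matrix(v, ncol = 1, dimnames = list(NULL, "0 to 1"))
  same <- mk(rnorm(40))
  out <- ks_per_bin(same, same)
  expect_equal(out$ks_stat, 0)
  expect_equal(out$p_value, 1)

  # strong shift: asymptotic, auto and permutation all agree it is real
  x <- mk(rnorm(100, 1)); y <- mk(rnorm(100, 0))
  expect_lt(ks_per_bin(x, y)$p_value, 0.01)
  expect_lt(ks_per_bin(x, y, method = "asymptotic")$p_value, 0.01)
  expect_lt(ks_per_bin(x, y, method = "permutation",
                       n_perm = 200)$p_value, 0.01)

  # type-I calibration at the cohort-scale n
  rej <- 0L
  for (r in 1:200) {
    p <- ks_per_bin(mk(rnorm(30)), mk(rnorm(30)))$p_value
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 200, 0.025)
  expect_lte(rej / 200, 0.08)

  # too few values flagged, not fatal
  small <- ks_per_bin(mk(rnorm(3)), mk(rnorm(30)))
  expect_true(small$insufficient)
  expect_true(is.na(small$p_value))
})

test_that("circular mean and resultant strength follow the definitions", {
  r1 <- circular_mean_R(rep(37, 5))
  expect_equal(r1$mean_deg, 37)
  expect_equal(r1$R, 1)

  expect_lt(circular_mean_R(c(0, 180))$R, 1e-12)

  set.seed(41)
  expect_lt(circular_mean_R(runif(1e4, -180, 180))$R, 0.03)

  # R is invariant to adding a constant
  a <- runif(500, -180, 180)
  expect_equal(circular_mean_R(a)$R, circular_mean_R(a + 77)$R,
               tolerance = 1e-12)
  expect_error(circular_mean_R(numeric(0)), "angle")
})

test_that("angular deviations wrap and shrink with post-onset SD", {
  fs <- 30
  # constant angle: all deviations zero
  const <- angle_series(seq(0, 60, by = 1 / fs),
                        rep(100, 60 * fs + 1))
  w <- extract_real_windows(const, make_events(c(20, 40)), cfg)
  dev <- angle_deviation_distributions(w, "real", cfg)
  expect_lt(max(abs(c(dev$before, dev$after))), 1e-9)

  # wrapping: angles straddling 180 give small deviations, not ~360
  expect_equal(wrap_deg(c(179, -179) - 180), c(-1, 1))

  # post-onset noise at half SD: after-distribution is tighter
  set.seed(55)
  t <- seq(0, 120, by = 1 / fs)
  on <- c(20, 50, 80, 105)
  sdv <- rep(40, length(t))
  for (o in on) sdv[t >= o & t < o + cfg$angle_mean_window] <- 20
  noisy <- angle_series(t, rnorm(length(t), 0, sdv))
  wn <- extract_real_windows(noisy, make_events(on), cfg)
  dv <- angle_deviation_distributions(wn, "real", cfg)
  expect_lt(circ_sd_deg(dv$after), circ_sd_deg(dv$before))
})

test_that("paired resultant-strength test finds drops and respects nulls", {
  fs <- 30
  t <- seq(0, 500, by = 1 / fs)
  on <- seq(20, 480, by = 15)
  set.seed(66)
  sdv <- rep(45, length(t))
  for (o in on) sdv[t >= o & t < o + cfg$angle_mean_window] <- 15
  ang <- angle_series(t, rnorm(length(t), 0, sdv))
  w <- extract_real_windows(ang, make_events(on), cfg)
  res <- paired_R_test(w, "real", cfg)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$median_diff, 0)   # R rises after onset

  # identical periods: reported as no effect
  constw <- extract_real_windows(angle_series(t, rep(25, length(t))),
                                 make_events(on), cfg)
  expect_equal(paired_R_test(constw, "real", cfg)$p_value, 1)
  expect_error(paired_R_test(w, "real",
                             analysis_config(window_half = 5,
                                             angle_mean_window = 3)),
               NA)
})

test_that("z-scored crossing rates are flat for Poisson, peak on a boost", {
  set.seed(77)
  pois_row <- function(rate, boost = 1) {
    n <- stats::rpois(1, rate * 10)
    cr <- runif(n, -5, 5)
    if (boost > 1) {
      nb <- stats::rpois(1, rate * (boost - 1) * 0.5)
      cr <- c(cr, runif(nb, 0, 0.5))
    }
    sort(cr)
  }
  flat <- replicate(200, pois_row(4), simplify = FALSE)
  z <- zscored_crossing_rate(flat, cfg)
  # per-point SEM is ~1/sqrt(200) = 0.07, so a flat curve keeps its mean
  # level near zero and single-point excursions within a few SEM
  expect_lt(mean(abs(z$mean)), 0.08)
  expect_lt(max(abs(z$mean)), 0.3)

  boosted <- replicate(200, pois_row(4, boost = 3), simplify = FALSE)
  zb <- zscored_crossing_rate(boosted, cfg)
  early <- zb$t >= 0 & zb$t < 0.5
  late <- abs(zb$t) > 2
  expect_gt(mean(zb$mean[early]), mean(zb$mean[late]) + 0.3)

  # rows without usable variance are excluded and counted
  z0 <- zscored_crossing_rate(list(numeric(0), runif(30, -5, 5)), cfg)
  expect_equal(z0$n_excluded, 1L)
  expect_equal(z0$n_used, 1L)
})
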