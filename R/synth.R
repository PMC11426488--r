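#' Ground truth for a synthetic trial
#'
#' Effect sizes injected around each true encounter onset. The source
#' analysis reports per-bin significance rather than effect magnitudes, so
#' the defaults are declared package assumptions chosen to produce effects
#' of the direction and timing reported for real animals: a pitch-amplitude
#' boost in the second before the encounter, an amplitude drop in the
#' second after, a frequency increase and a head lowering for three seconds
#' after, and a reduction of heading-angle variability for three seconds
#' after.
#'
#' @param true_onsets encounter onset times, s (filled by [gen_trial()]).
#' @param amp_boost_pre multiplicative factor on the pitch-oscillation
#'   amplitude during the 1 s before each onset (default 1.5).
#' @param amp_drop_post factor during the 1 s after each onset (default 0.6).
#' @param freq_shift_post Hz added to the pitch-oscillation frequency for
#'   3 s after each onset (default 3).
#' @param head_drop_post change of the Z-minus-X head-height baseline for
#'   3 s after each onset, g (default -0.2, i.e. head lowering).
#' @param heading_var_drop_post factor on the heading-angle noise SD for
#'   3 s after each onset (default 0.3).
#' @param null_mode if TRUE all factors are forced to 1 and all shifts to
#'   0 (no modulation; the null condition).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(true_onsets = numeric(0), amp_boost_pre = 1.5,
                         amp_drop_post = 0.6, freq_shift_post = 3,
                         head_drop_post = -0.2, heading_var_drop_post = 0.3,
                         null_mode = FALSE) {
  if (isTRUE(null_mode)) {
    amp_boost_pre <- 1; amp_drop_post <- 1; freq_shift_post <- 0
    head_drop_post <- 0; heading_var_drop_post <- 1
  }
  if (amp_boost_pre <= 0 || amp_drop_post <= 0 || heading_var_drop_post <= 0) {
    stop("modulation factors must be > 0", call. = FALSE)
  }
  structure(list(true_onsets = as.numeric(true_onsets),
                 amp_boost_pre = amp_boost_pre,
                 amp_drop_post = amp_drop_post,
                 freq_shift_post = freq_shift_post,
                 head_drop_post = head_drop_post,
                 heading_var_drop_post = heading_var_drop_post,
                 null_mode = isTRUE(null_mode)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("<ground_truth> %d onsets%s: amp pre x%g / post x%g, ",
                     "freq +%g Hz, head %+g g, heading SD x%g\n"),
              length(x$true_onsets), if (x$null_mode) " (null mode)" else "",
              x$amp_boost_pre, x$amp_drop_post, x$freq_shift_post,
              x$head_drop_post, x$heading_var_drop_post))
  invisible(x)
}

#' Schedule synthetic encounter onsets
#'
#' Onsets are scheduled (not emergent from plume physics): a Poisson-like
#' renewal process with a refractory interval of twice the minimum event
#' separation, keeping exact ground truth. All onsets lie at least
#' `window_half` (plus a small margin) from the trial edges.
#'
#' @param duration trial duration, s.
#' @param config an [analysis_config()].
#' @param seed integer seed.
#' @param mean_extra_gap mean of the exponential gap added to the
#'   refractory interval, s (default 10).
#' @return Sorted onset times, s.
#' @export
schedule_onsets <- function(duration, config = analysis_config(), seed = 1L,
                            mean_extra_gap = 10) {
  margin <- config$window_half + 0.5
  refractory <- 2 * config$min_event_separation
  if (duration <= 2 * margin) return(numeric(0))
  with_seed(seed, {
    onsets <- numeric(0)
    t <- margin + stats::rexp(1, 1 / mean_extra_gap)
    while (t <= duration - margin) {
      onsets <- c(onsets, t)
      t <- t + refractory + stats::rexp(1, 1 / mean_extra_gap)
    }
    onsets
  })
}

#' Synthesize a gas-sensor trace
#'
#' The instantaneous odor concentration is a sum of unit-height
#' rectangular "whiffs" (duration `whiff_duration`) starting at the true
#' onsets --- or unit-mass impulses with `shape = "impulse"` --- convolved
#' with the difference-of-exponentials sensor kernel, plus a slow sinusoidal
#' drift (emulating temperature effects on the sensor over long time
#' scales) and white Gaussian measurement noise.
#'
#' @param true_onsets sorted onset times, s, inside `(0, duration)`.
#' @param config an [analysis_config()].
#' @param seed integer seed.
#' @param duration trace duration, s.
#' @param noise_sd measurement noise SD, sensor units (default 2.5e-4,
#'   roughly DAQ/electronic noise relative to a whiff response of ~0.2).
#' @param drift_amp slow-drift amplitude (default 5 x `noise_sd`).
#' @param drift_period drift period, s (>= 60; default 90).
#' @param shape `"whiff"` (default) or `"impulse"`.
#' @param whiff_duration rectangular whiff duration, s.
#' @param amplitude whiff height (or impulse mass).
#' @return A single-channel `plume_ts` (the raw sensor voltage analogue).
#' @export
gen_sensor_trace <- function(true_onsets, config = analysis_config(),
                             seed = 1L, duration = 120,
                             noise_sd = 2.5e-4, drift_amp = 5 * noise_sd,
                             drift_period = 90,
                             shape = c("whiff", "impulse"),
                             whiff_duration = 2, amplitude = 1) {
  shape <- match.arg(shape)
  if (is.unsorted(true_onsets)) stop("onsets must be sorted", call. = FALSE)
  if (any(true_onsets < 0 | true_onsets >= duration)) {
    stop("onset outside the trace duration", call. = FALSE)
  }
  fs <- config$fs_sensor
  n <- as.integer(round(duration * fs))
  conc <- numeric(n)
  for (o in true_onsets) {
    i0 <- as.integer(round(o * fs)) + 1L
    if (shape == "whiff") {
      i1 <- min(n, i0 + as.integer(round(whiff_duration * fs)) - 1L)
      conc[i0:i1] <- conc[i0:i1] + amplitude
    } else {
      conc[i0] <- conc[i0] + amplitude * fs   # unit-mass discrete impulse
    }
  }
  clean <- convolve_kernel(time_series(conc, fs), config$tau_rise,
                           config$tau_decay)$values[, 1]
  t <- (seq_len(n) - 1L) / fs
  with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    drift <- drift_amp * sin(2 * pi * t / drift_period + phase)
    noise <- stats::rnorm(n, 0, noise_sd)
    time_series(clean + drift + noise, fs)
  })
}

#' Alternating head-raised / head-lowered schedule
#'
#' Exponentially distributed dwell times, alternating states.
#'
#' @param duration schedule span, s.
#' @param seed integer seed.
#' @param mean_dwell mean dwell time per state, s.
#' @return A data frame: `state` ("raised"/"lowered"), `start`, `end`.
#' @export
gen_head_state_schedule <- function(duration, seed = 1L, mean_dwell = 4) {
  with_seed(seed, {
    states <- character(0); starts <- numeric(0); ends <- numeric(0)
    t <- 0
    st <- sample(c("raised", "lowered"), 1L)
    while (t < duration) {
      dwell <- stats::rexp(1, 1 / mean_dwell)
      states <- c(states, st)
      starts <- c(starts, t)
      ends <- c(ends, min(t + dwell, duration))
      t <- t + dwell
      st <- if (st == "raised") "lowered" else "raised"
    }
    data.frame(state = states, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
}

# multiplicative / additive modulation envelopes around onsets
onset_envelope <- function(t, onsets, from, to, value, base, mode) {
  out <- rep(base, length(t))
  for (o in onsets) {
    sel <- t >= o + from & t < o + to
    out[sel] <- if (mode == "mult") out[sel] * value else out[sel] + value
  }
  out
}

#' Synthesize a 3-axis accelerometer trace
#'
#' The X channel (gravity-aligned) carries a state-dependent gravity
#' baseline plus a pitch oscillation in the active-search range (default
#' 8 Hz, amplitude 0.05 g); the Z channel carries the complementary
#' gravity projection plus an attenuated copy of the oscillation; Y is
#' noise only. Ground-truth modulations: the oscillation amplitude is
#' multiplied by `amp_boost_pre` during the 1 s before each onset and by
#' `amp_drop_post` during the 1 s after; its frequency gains
#' `freq_shift_post` Hz for 3 s after; the Z-minus-X baseline shifts by
#' `head_drop_post` g for 3 s after.
#'
#' @param true_onsets onset times, s.
#' @param schedule head-state schedule from [gen_head_state_schedule()];
#'   NULL for a single permanently "raised" epoch.
#' @param truth a [ground_truth()].
#' @param config an [analysis_config()].
#' @param seed integer seed.
#' @param duration trace duration, s.
#' @param pitch_freq base pitch-oscillation frequency, Hz.
#' @param pitch_amp base oscillation amplitude, g.
#' @param noise_sd per-channel sensor noise SD, g.
#' @param base_raised,base_lowered `c(X, Z)` gravity baselines per state, g.
#' @return A 3-channel `plume_ts` in g (channels x, y, z).
#' @export
gen_accel_trace <- function(true_onsets, schedule, truth,
                            config = analysis_config(), seed = 1L,
                            duration = 120, pitch_freq = 8,
                            pitch_amp = 0.05, noise_sd = 0.02,
                            base_raised = c(0.25, 0.40),
                            base_lowered = c(0.60, 0.05)) {
  stopifnot(inherits(truth, "ground_truth"))
  fs <- config$fs_accel
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1L) / fs
  if (is.null(schedule)) {
    schedule <- data.frame(state = "raised", start = 0, end = duration)
  }
  if (min(schedule$start) > 0 || max(schedule$end) < duration) {
    stop("head-state schedule must cover the trace duration", call. = FALSE)
  }
  baseX <- numeric(n); baseZ <- numeric(n)
  for (r in seq_len(nrow(schedule))) {
    sel <- t >= schedule$start[r] & t < schedule$end[r]
    bb <- if (schedule$state[r] == "raised") base_raised else base_lowered
    baseX[sel] <- bb[1]; baseZ[sel] <- bb[2]
  }
  # head-height change: split the d = Z - X offset between the two axes
  dshift <- onset_envelope(t, true_onsets, 0, 3, truth$head_drop_post, 0, "add")
  baseZ <- baseZ + dshift / 2
  baseX <- baseX - dshift / 2
  amp <- pitch_amp *
    onset_envelope(t, true_onsets, -1, 0, truth$amp_boost_pre, 1, "mult") *
    onset_envelope(t, true_onsets, 0, 1, truth$amp_drop_post, 1, "mult")
  freq <- onset_envelope(t, true_onsets, 0, 3, truth$freq_shift_post,
                         pitch_freq, "add")
  with_seed(seed, {
    phi0 <- stats::runif(1, 0, 2 * pi)
    phase <- phi0 + 2 * pi * cumsum(freq) / fs
    osc <- amp * sin(phase)
    x <- baseX + osc + stats::rnorm(n, 0, noise_sd)
    y <- stats::rnorm(n, 0, noise_sd)
    z <- baseZ + 0.4 * osc + stats::rnorm(n, 0, noise_sd)
    time_series(cbind(x, y, z), fs, channels = c("x", "y", "z"))
  })
}

#' Synthesize a keypoint trajectory
#'
#' A correlated random walk from an entry point toward the odor port: the
#' heading is the instantaneous angle to the port plus an AR(1) angular
#' bias whose stationary SD is `heading_sd_deg`, multiplied by the
#' ground-truth `heading_var_drop_post` for 3 s after each onset. Nose,
#' neck and body keypoints are placed along the heading at fixed segment
#' lengths, with a sinusoidal head-yaw wobble superimposed on the nose.
#' Likelihoods are 1 except a configured fraction of frames dropped to 0.5.
#'
#' @param config an [analysis_config()].
#' @param truth a [ground_truth()].
#' @param true_onsets onset times, s.
#' @param seed integer seed.
#' @param duration trajectory duration, s.
#' @param arena_bounds `c(xmin, ymin, xmax, ymax)`, px.
#' @param port_xy odor-port position, px.
#' @param entry_xy entry point, px.
#' @param speed_px walking speed, px/s.
#' @param heading_sd_deg stationary SD of the heading bias, degrees.
#' @param heading_tau AR(1) correlation time of the bias, s.
#' @param yaw_amp,yaw_freq,yaw_noise_deg head-yaw wobble amplitude (deg),
#'   frequency (Hz) and per-frame angular noise SD (deg).
#' @param dropout_frac fraction of frames with likelihood 0.5.
#' @param seg_neck_body,seg_nose_neck body segment lengths, px.
#' @return A list: `track` ([keypoint_track()]), `port_xy`, `arena_bounds`,
#'   `heading_bias_deg` (the per-frame ground-truth body-angle bias).
#' @export
gen_trajectory <- function(config = analysis_config(), truth = ground_truth(),
                           true_onsets = truth$true_onsets, seed = 1L,
                           duration = 120,
                           arena_bounds = c(0, 0, 800, 800),
                           port_xy = c(740, 400), entry_xy = c(60, 400),
                           speed_px = 6, heading_sd_deg = 40,
                           heading_tau = 0.5, yaw_amp = 25, yaw_freq = 2,
                           yaw_noise_deg = 8, dropout_frac = 0.02,
                           seg_neck_body = 15, seg_nose_neck = 10) {
  stopifnot(inherits(truth, "ground_truth"))
  if (arena_bounds[3] <= arena_bounds[1] || arena_bounds[4] <= arena_bounds[2]) {
    stop("arena dimensions must be positive", call. = FALSE)
  }
  if (port_xy[1] < arena_bounds[1] || port_xy[1] > arena_bounds[3] ||
      port_xy[2] < arena_bounds[2] || port_xy[2] > arena_bounds[4]) {
    stop("port outside the arena", call. = FALSE)
  }
  fps <- config$fps_video
  dt <- 1 / fps
  n <- as.integer(round(duration * fps))
  tt <- (seq_len(n) - 1L) / fps
  rho <- exp(-dt / heading_tau)
  sd_frame <- onset_envelope(tt, true_onsets, 0, 3,
                             truth$heading_var_drop_post, 1, "mult") *
    heading_sd_deg
  onset_frames <- unique(pmin(pmax(as.integer(round(true_onsets * fps)) + 1L,
                                   1L), n))
  with_seed(seed, {
    innov <- stats::rnorm(n)
    yaw_noise <- stats::rnorm(n, 0, yaw_noise_deg)
    drop <- stats::runif(n) < dropout_frac
    b <- numeric(n)
    b[1] <- stats::rnorm(1, 0, sd_frame[1])
    for (i in 2:n) {
      b[i] <- rho * b[i - 1L] + sqrt(1 - rho^2) * sd_frame[i] * innov[i]
      if (i %in% onset_frames && truth$heading_var_drop_post != 1) {
        b[i] <- b[i] * truth$heading_var_drop_post
      }
    }
    x <- numeric(n); y <- numeric(n)
    x[1] <- entry_xy[1]; y[1] <- entry_xy[2]
    heading <- numeric(n)
    pad <- 5
    for (i in seq_len(n)) {
      a2p <- atan2(port_xy[2] - y[i], port_xy[1] - x[i])
      heading[i] <- a2p + b[i] * pi / 180
      if (i < n) {
        x[i + 1L] <- min(max(x[i] + speed_px * dt * cos(heading[i]),
                             arena_bounds[1] + pad), arena_bounds[3] - pad)
        y[i + 1L] <- min(max(y[i] + speed_px * dt * sin(heading[i]),
                             arena_bounds[2] + pad), arena_bounds[4] - pad)
      }
    }
    yaw <- (yaw_amp * sin(2 * pi * yaw_freq * tt) + yaw_noise) * pi / 180
    bx <- x; by <- y
    nkx <- bx + seg_neck_body * cos(heading)
    nky <- by + seg_neck_body * sin(heading)
    nsx <- nkx + seg_nose_neck * cos(heading + yaw)
    nsy <- nky + seg_nose_neck * sin(heading + yaw)
    p <- ifelse(drop, 0.5, 1.0)
    track <- keypoint_track(data.frame(
      nose_x = nsx, nose_y = nsy, nose_p = p,
      neck_x = nkx, neck_y = nky, neck_p = p,
      body_x = bx, body_y = by, body_p = p), fps = fps)
    list(track = track, port_xy = port_xy, arena_bounds = arena_bounds,
         heading_bias_deg = b)
  })
}

#' Assemble one synthetic trial
#'
#' Schedules onsets, then generates the sensor, accelerometer and keypoint
#' streams on a shared timeline. Deterministic given `(config, truth,
#' seed)`.
#'
#' @param config an [analysis_config()].
#' @param truth a [ground_truth()] (its `true_onsets` are replaced by the
#'   scheduled ones).
#' @param seed integer seed.
#' @param duration trial duration, s.
#' @param trial_id id string.
#' @param sensor_args,accel_args,trajectory_args named lists of overrides
#'   passed to the stream generators.
#' @return An object of class `synthetic_trial`: `trial` (a
#'   [trial_record()]), `truth` (with onsets filled), `schedule`.
#' @export
gen_trial <- function(config = analysis_config(), truth = ground_truth(),
                      seed = 1L, duration = 120, trial_id = "trial_001",
                      sensor_args = list(), accel_args = list(),
                      trajectory_args = list()) {
  seed <- as.integer(seed %% 2147480000)
  onsets <- schedule_onsets(duration, config, seed = seed + 1L)
  truth$true_onsets <- onsets
  sensor <- do.call(gen_sensor_trace, c(list(
    true_onsets = onsets, config = config, seed = seed + 2L,
    duration = duration), sensor_args))
  schedule <- gen_head_state_schedule(duration, seed = seed + 3L)
  accel <- do.call(gen_accel_trace, c(list(
    true_onsets = onsets, schedule = schedule, truth = truth,
    config = config, seed = seed + 4L, duration = duration), accel_args))
  traj <- do.call(gen_trajectory, c(list(
    config = config, truth = truth, true_onsets = onsets, seed = seed + 5L,
    duration = duration), trajectory_args))
  trial <- trial_record(trial_id, sensor, accel, traj$track, traj$port_xy,
                        traj$arena_bounds, c(0, duration))
  structure(list(trial = trial, truth = truth, schedule = schedule),
            class = "synthetic_trial")
}

#' Generate a cohort of synthetic trials
#'
#' Per-trial seeds are drawn deterministically from the master seed, so the
#' cohort is reproducible and trials are independent.
#'
#' @inheritParams gen_trial
#' @param n_trials number of trials (>= 1).
#' @return A list of `synthetic_trial`s.
#' @export
gen_cohort <- function(config = analysis_config(), truth = ground_truth(),
                       n_trials = 30L, seed = 1L, duration = 120, ...) {
  if (n_trials < 1L) stop("'n_trials' must be >= 1", call. = FALSE)
  sub <- with_seed(seed, sample.int(2147480000L, n_trials))
  lapply(seq_len(n_trials), function(i) {
    gen_trial(config, truth, seed = sub[i], duration = duration,
              trial_id = sprintf("trial_%03d", i), ...)
  })
}

#' Write ground truth to CSV
#'
#' Onset times as rows; the scalar effect sizes as `#`-comment header
#' metadata.
#'
#' @param truth a [ground_truth()].
#' @param path CSV path.
#' @export
write_ground_truth_csv <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in c("amp_boost_pre", "amp_drop_post", "freq_shift_post",
              "head_drop_post", "heading_var_drop_post", "null_mode")) {
    writeLines(sprintf("# %s=%s", f, format(truth[[f]])), con)
  }
  writeLines("onset_s", con)
  writeLines(sprintf("%.17g", truth$true_onsets), con)
  invisible(path)
}

#' @rdname write_ground_truth_csv
#' @export
read_ground_truth_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", meta), "="))
  vals <- as.list(kv[, 2])
  names(vals) <- kv[, 1]
  body <- lines[!grepl("^# ", lines)]
  onsets <- as.numeric(body[-1L])
  ground_truth(true_onsets = onsets[!is.na(onsets)],
               amp_boost_pre = as.numeric(vals$amp_boost_pre),
               amp_drop_post = as.numeric(vals$amp_drop_post),
               freq_shift_post = as.numeric(vals$freq_shift_post),
               head_drop_post = as.numeric(vals$head_drop_post),
               heading_var_drop_post = as.numeric(vals$heading_var_drop_post),
               null_mode = as.logical(vals$null_mode))
}
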