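#' Process a single trial through the signal stages
#'
#' Runs the sensor chain (low-pass, deconvolution, slope-ratio detection,
#' group-data filters), the head-motion chain (jerk of the gravity-aligned
#' axis, wavelet band power and dominant frequency, Z-minus-X head height)
#' and the kinematics chain (likelihood masking, body angle, head yaw,
#' speed, yaw zero crossings).
#'
#' @param trial a [trial_record()] (or a `synthetic_trial`).
#' @param config an [analysis_config()].
#' @param threshold optional detection-threshold override.
#' @return A list of per-trial products: `events`, `deconv`, `band_power`
#'   (`plume_ts`), `dominant_freq` (`plume_ts`), `head_d` (`plume_ts`),
#'   `body` and `yaw` ([angle_series()]), `speed`, `crossing_times`,
#'   `in_arena`, `trial_id`.
#' @export
process_trial <- function(trial, config = analysis_config(),
                          threshold = NULL) {
  if (inherits(trial, "synthetic_trial")) trial <- trial$trial
  stopifnot(inherits(trial, "trial_record"))
  filt <- lowpass(trial$sensor, config$lp_sensor_cutoff)
  deconv <- deconvolve(filt, config$tau_rise, config$tau_decay,
                       config$deconv_lambda)
  ev <- detect_events(deconv, config, threshold = threshold)
  ev <- filter_events(ev, trial$keypoints, trial$port_xy, trial$in_arena,
                      config)
  jk <- jerk(trial$accel, config)
  jx <- time_series(jk$values[, 1], jk$fs, jk$t0)
  bp <- cwt_band_power(jx, config)
  head_d <- head_height_signal(trial$accel, config)
  masked <- mask_low_likelihood(trial$keypoints, config$likelihood_min)
  body <- body_angle(masked, trial$port_xy, config)
  yaw <- head_yaw(masked)
  list(trial_id = trial$trial_id,
       events = ev,
       deconv = deconv,
       band_power = time_series(bp$power, jx$fs, jx$t0),
       dominant_freq = time_series(bp$dominant_freq, jx$fs, jx$t0),
       head_d = head_d,
       body = body,
       yaw = yaw,
       speed = speed(masked, config$speed_smooth_window),
       crossing_times = zero_crossings(yaw),
       in_arena = trial$in_arena)
}

crossings_relative <- function(crossing_times, onsets, window_half) {
  lapply(onsets, function(o) {
    cr <- crossing_times[crossing_times >= o - window_half &
                           crossing_times <= o + window_half]
    cr - o
  })
}

#' Cohort-level peri-encounter analysis
#'
#' Pools real and surrogate peri-event windows across trials and runs the
#' full statistical battery: per-bin KS tables for band power, head
#' height, dominant frequency and z-scored crossing rate (the statistics
#' table layout), circular summaries and paired Wilcoxon resultant-strength
#' tests for the body and head-yaw angles, and mean z-scored crossing-rate
#' curves. One set of surrogate onsets is drawn per trial (as many as that
#' trial's retained real events) and shared across all series.
#'
#' @param trials list of [trial_record()]s or `synthetic_trial`s.
#' @param config an [analysis_config()].
#' @param seed integer seed for the surrogate draws.
#' @param threshold optional detection-threshold override.
#' @param processed optional pre-computed list from [process_trial()].
#' @return An object of class `cohort_analysis`; see Details.
#' @details The returned list carries `bins` (named list of
#'   `bin_comparison` tables), `windows` (pooled `peri_event_set`s per
#'   parameter), `body_R`, `yaw_R` (paired tests for real and random
#'   windows), `body_deviation` (before/after pooled deviations),
#'   `body_curves`, `yaw_curves` (per-time circular summaries),
#'   `crossing_rate` (real/random mean curves), `n_events`, `n_trials`.
#' @export
analyze_cohort <- function(trials, config = analysis_config(), seed = 1L,
                           threshold = NULL, processed = NULL) {
  if (is.null(processed)) {
    processed <- lapply(trials, process_trial, config = config,
                        threshold = threshold)
  }
  seed <- as.integer(seed %% 2147480000)
  scalar_params <- c("band_power", "dominant_freq", "head_d")
  angle_params <- c("body", "yaw")
  sets <- list()
  cross_real <- list()
  cross_rand <- list()
  for (i in seq_along(processed)) {
    pr <- processed[[i]]
    n_ev <- sum(pr$events$retained)
    if (n_ev == 0L) next
    rand_t <- sample_random_onsets(pr$events, pr$in_arena, config,
                                   seed = seed + i)
    for (p in c(scalar_params, angle_params)) {
      real <- extract_real_windows(pr[[p]], pr$events, config)
      rand <- windows_at(pr[[p]], rand_t, config, role = "random")
      sets[[p]] <- c(sets[[p]], list(peri_event_set(real, rand)))
    }
    onsets <- retained_onsets(pr$events)
    cross_real <- c(cross_real,
                    crossings_relative(pr$crossing_times, onsets,
                                       config$window_half))
    cross_rand <- c(cross_rand,
                    crossings_relative(pr$crossing_times, rand_t,
                                       config$window_half))
  }
  if (length(sets) == 0L) {
    stop("no retained events in the cohort; nothing to analyze",
         call. = FALSE)
  }
  pooled <- lapply(sets, pool_peri_event_sets)

  bins <- list()
  for (p in scalar_params) {
    bins[[p]] <- ks_per_bin(bin_means(pooled[[p]], "real", config),
                            bin_means(pooled[[p]], "random", config))
  }
  cr_real_rows <- crossing_rate_rows(cross_real, config)
  cr_rand_rows <- crossing_rate_rows(cross_rand, config)
  if (nrow(cr_real_rows$z) >= 5L && nrow(cr_rand_rows$z) >= 5L) {
    bins$crossing_rate <- ks_per_bin(
      bin_means_matrix(cr_real_rows$z, cr_real_rows$t, config),
      bin_means_matrix(cr_rand_rows$z, cr_rand_rows$t, config))
  }

  structure(list(
    bins = bins,
    windows = pooled,
    body_R = list(real = paired_R_test(pooled$body, "real", config),
                  random = paired_R_test(pooled$body, "random", config)),
    yaw_R = list(real = paired_R_test(pooled$yaw, "real", config),
                 random = paired_R_test(pooled$yaw, "random", config)),
    body_deviation = list(
      real = angle_deviation_distributions(pooled$body, "real", config),
      random = angle_deviation_distributions(pooled$body, "random", config)),
    body_curves = list(
      real = circular_summary_columns(pooled$body$real),
      random = circular_summary_columns(pooled$body$random)),
    yaw_curves = list(
      real = circular_summary_columns(pooled$yaw$real),
      random = circular_summary_columns(pooled$yaw$random)),
    crossing_rate = list(real = zscored_crossing_rate(cross_real, config),
                         random = zscored_crossing_rate(cross_rand, config)),
    n_events = nrow(pooled$band_power$real),
    n_trials = length(processed),
    processed = processed),
    class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d trials, %d pooled events\n",
              x$n_trials, x$n_events))
  cat(sprintf("  body-angle paired R: real p = %.3g, random p = %.3g\n",
              x$body_R$real$p_value, x$body_R$random$p_value))
  for (p in names(x$bins)) {
    sig <- sum(x$bins[[p]]$p_value < 0.05, na.rm = TRUE)
    cat(sprintf("  %-14s significant bins (p < 0.05): %d / %d\n",
                p, sig, nrow(x$bins[[p]])))
  }
  invisible(x)
}

# ---- file-based pipeline stages -------------------------------------------

trial_paths <- function(dir, id) {
  list(sensor = file.path(dir, paste0(id, "_sensor.csv")),
       accel = file.path(dir, paste0(id, "_accel.csv")),
       keypoints = file.path(dir, paste0(id, "_keypoints.csv")),
       meta = file.path(dir, paste0(id, "_meta.yaml")),
       truth = file.path(dir, paste0(id, "_truth.csv")),
       events = file.path(dir, paste0(id, "_events.csv")),
       bandpower = file.path(dir, paste0(id, "_bandpower.csv")),
       headstate = file.path(dir, paste0(id, "_headstate.csv")),
       angles = file.path(dir, paste0(id, "_angles.csv")),
       crossings = file.path(dir, paste0(id, "_crossings.csv")),
       speed = file.path(dir, paste0(id, "_speed.csv")))
}

list_trial_ids <- function(dir) {
  f <- sort(list.files(dir, pattern = "_sensor\\.csv$"))
  sub("_sensor\\.csv$", "", f)
}

stage_error <- function(stage, id, e) {
  stop(sprintf("stage '%s' failed for trial '%s': %s", stage, id,
               conditionMessage(e)), call. = FALSE)
}

#' Pipeline stage: generate a synthetic cohort
#'
#' Writes per-trial sensor, accelerometer and keypoint CSVs, a metadata
#' YAML and the ground-truth CSV into `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param config an [analysis_config()].
#' @param n_trials cohort size.
#' @param seed master seed.
#' @param truth a [ground_truth()].
#' @param duration trial duration, s.
#' @param ... forwarded to [gen_cohort()].
#' @return Invisibly, the trial ids written.
#' @export
stage_generate <- function(out_dir, config = analysis_config(),
                           n_trials = 30L, seed = config$rng_seed,
                           truth = ground_truth(), duration = 120, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- gen_cohort(config, truth, n_trials = n_trials, seed = seed,
                       duration = duration, ...)
  for (st in cohort) {
    id <- st$trial$trial_id
    p <- trial_paths(out_dir, id)
    tryCatch({
      write_timeseries_csv(st$trial$sensor, p$sensor)
      write_timeseries_csv(st$trial$accel, p$accel)
      write_keypoint_csv(st$trial$keypoints, p$keypoints)
      yaml::write_yaml(list(trial_id = id,
                            port_xy = st$trial$port_xy,
                            arena_bounds = st$trial$arena_bounds,
                            in_arena = as.vector(t(st$trial$in_arena)),
                            fps = st$trial$keypoints$fps),
                       p$meta)
      write_ground_truth_csv(st$truth, p$truth)
    }, error = function(e) stage_error("generate", id, e))
  }
  invisible(vapply(cohort, function(s) s$trial$trial_id, character(1)))
}

read_trial_meta <- function(dir, id) {
  p <- trial_paths(dir, id)
  if (!file.exists(p$meta)) {
    stop("missing metadata file for trial '", id, "': ", p$meta,
         call. = FALSE)
  }
  meta <- yaml::read_yaml(p$meta)
  meta$in_arena <- matrix(as.numeric(meta$in_arena), ncol = 2L, byrow = TRUE)
  meta
}

load_trial <- function(dir, id) {
  p <- trial_paths(dir, id)
  for (f in c("sensor", "accel", "keypoints")) {
    if (!file.exists(p[[f]])) {
      stop("missing ", f, " CSV for trial '", id, "': ", p[[f]],
           call. = FALSE)
    }
  }
  meta <- read_trial_meta(dir, id)
  trial_record(id,
               sensor = read_timeseries_csv(p$sensor),
               accel = read_timeseries_csv(p$accel),
               keypoints = read_keypoint_csv(p$keypoints, fps = meta$fps),
               port_xy = as.numeric(meta$port_xy),
               arena_bounds = as.numeric(meta$arena_bounds),
               in_arena = meta$in_arena)
}

#' Pipeline stage: detect plume encounters
#'
#' Reads each trial's sensor trace, runs low-pass + deconvolution +
#' slope-ratio detection + group-data filters, and writes the events CSV.
#'
#' @param data_dir directory with the trial CSVs.
#' @param out_dir directory for the events CSVs.
#' @param config an [analysis_config()].
#' @param threshold optional detection-threshold override.
#' @return Invisibly, the trial ids processed.
#' @export
stage_detect <- function(data_dir, out_dir = data_dir,
                         config = analysis_config(), threshold = NULL) {
  ids <- list_trial_ids(data_dir)
  if (length(ids) == 0L) stop("no trial sensor CSVs found in ", data_dir,
                              call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in ids) {
    tryCatch({
      trial <- load_trial(data_dir, id)
      filt <- lowpass(trial$sensor, config$lp_sensor_cutoff)
      dec <- deconvolve(filt, config$tau_rise, config$tau_decay,
                        config$deconv_lambda)
      ev <- detect_events(dec, config, threshold = threshold)
      ev <- filter_events(ev, trial$keypoints, trial$port_xy,
                          trial$in_arena, config)
      write_events_csv(ev, trial_paths(out_dir, id)$events)
    }, error = function(e) stage_error("detect", id, e))
  }
  invisible(ids)
}

#' Pipeline stage: head-motion measures
#'
#' Writes per-trial band-power/dominant-frequency CSVs and, after pooling
#' the Z-minus-X head-height samples over the whole cohort, fits the
#' Gaussian-mixture head-state threshold and writes per-trial head-state
#' CSVs plus the mixture parameters.
#'
#' @inheritParams stage_detect
#' @return Invisibly, the fitted `gmm_fit` (NULL if the pooled sample was
#'   too small, in which case heads are classified against the median).
#' @export
stage_headmotion <- function(data_dir, out_dir = data_dir,
                             config = analysis_config()) {
  ids <- list_trial_ids(data_dir)
  if (length(ids) == 0L) stop("no trial sensor CSVs found in ", data_dir,
                              call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dsigs <- list()
  for (id in ids) {
    tryCatch({
      p <- trial_paths(data_dir, id)
      if (!file.exists(p$accel)) {
        stop("missing accel CSV: ", p$accel, call. = FALSE)
      }
      accel <- read_timeseries_csv(p$accel)
      jk <- jerk(accel, config)
      jx <- time_series(jk$values[, 1], jk$fs, jk$t0)
      bp <- cwt_band_power(jx, config)
      write_results_csv(data.frame(t = bp$t, band_power = bp$power,
                                   dominant_freq = bp$dominant_freq),
                        trial_paths(out_dir, id)$bandpower)
      dsigs[[id]] <- head_height_signal(accel, config)
    }, error = function(e) stage_error("headmotion", id, e))
  }
  pooled <- unlist(lapply(dsigs, function(d) d$values[, 1]))
  fit <- NULL
  thr <- stats::median(pooled)
  if (length(pooled) >= 1000L) {
    fit <- fit_head_state_threshold(pooled, config)
    thr <- fit$threshold
    yaml::write_yaml(list(k = fit$k, weights = fit$weights,
                          means = fit$means, sds = fit$sds,
                          bic = as.list(fit$bic), threshold = thr),
                     file.path(out_dir, "head_state_gmm.yaml"))
  }
  for (id in ids) {
    hs <- classify_head_state(dsigs[[id]], thr)
    write_results_csv(data.frame(t = hs$t, d = hs$d, raised = hs$raised),
                      trial_paths(out_dir, id)$headstate)
  }
  invisible(fit)
}

#' Pipeline stage: keypoint kinematics
#'
#' Writes per-trial angle, zero-crossing and speed CSVs.
#'
#' @inheritParams stage_detect
#' @return Invisibly, the trial ids processed.
#' @export
stage_kinematics <- function(data_dir, out_dir = data_dir,
                             config = analysis_config()) {
  ids <- list_trial_ids(data_dir)
  if (length(ids) == 0L) stop("no trial sensor CSVs found in ", data_dir,
                              call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in ids) {
    tryCatch({
      p <- trial_paths(data_dir, id)
      meta <- read_trial_meta(data_dir, id)
      track <- read_keypoint_csv(p$keypoints, fps = meta$fps)
      masked <- mask_low_likelihood(track, config$likelihood_min)
      body <- body_angle(masked, as.numeric(meta$port_xy), config)
      yaw <- head_yaw(masked)
      po <- trial_paths(out_dir, id)
      write_results_csv(data.frame(t = body$t,
                                   body_angle_deg = body$deg,
                                   head_yaw_deg = yaw$deg,
                                   valid = body$valid & yaw$valid),
                        po$angles)
      write_results_csv(data.frame(t_cross = zero_crossings(yaw)),
                        po$crossings)
      sp <- speed(masked, config$speed_smooth_window)
      write_results_csv(data.frame(t = ts_time(sp),
                                   speed_px_s = sp$values[, 1]),
                        po$speed)
    }, error = function(e) stage_error("kinematics", id, e))
  }
  invisible(ids)
}

#' Pipeline stage: peri-encounter statistics
#'
#' Reads the per-trial intermediate CSVs (events, band power, head state,
#' angles), builds pooled real and surrogate windows, and writes the
#' result tables: the per-bin KS table across parameters (statistics-table
#' layout), mean-angle/resultant-strength curves, paired resultant
#' strengths, and z-scored crossing-rate curves.
#'
#' @inheritParams stage_detect
#' @param seed seed for the surrogate draws.
#' @return Invisibly, a `cohort_analysis`.
#' @export
stage_analyze <- function(data_dir, out_dir = data_dir,
                          config = analysis_config(),
                          seed = config$rng_seed) {
  ids <- list_trial_ids(data_dir)
  if (length(ids) == 0L) stop("no trial sensor CSVs found in ", data_dir,
                              call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  processed <- list()
  for (id in ids) {
    tryCatch({
      p <- trial_paths(data_dir, id)
      for (f in c("events", "bandpower", "headstate", "angles",
                  "crossings")) {
        if (!file.exists(p[[f]])) {
          stop("missing ", f, " CSV (run the earlier stages first): ",
               p[[f]], call. = FALSE)
        }
      }
      meta <- read_trial_meta(data_dir, id)
      ev <- read_events_csv(p$events)
      bp <- read_timeseries_csv(p$bandpower)
      hs <- utils::read.csv(p$headstate)
      ang <- utils::read.csv(p$angles)
      fs_bp <- bp$fs
      fs_ang <- 1 / stats::median(diff(ang$t))
      crossings <- utils::read.csv(p$crossings)$t_cross
      processed[[id]] <- list(
        trial_id = id,
        events = ev,
        band_power = time_series(bp$values[, "band_power"], fs_bp, bp$t0),
        dominant_freq = time_series(bp$values[, "dominant_freq"], fs_bp,
                                    bp$t0),
        head_d = time_series(hs$d, fs_bp, hs$t[1]),
        body = angle_series(ang$t, ang$body_angle_deg,
                            as.logical(ang$valid)),
        yaw = angle_series(ang$t, ang$head_yaw_deg, as.logical(ang$valid)),
        speed = NULL,
        crossing_times = as.numeric(crossings),
        in_arena = meta$in_arena)
    }, error = function(e) stage_error("analyze", id, e))
  }
  res <- analyze_cohort(NULL, config, seed = seed, processed = processed)
  write_analysis_outputs(res, out_dir)
  invisible(res)
}

write_analysis_outputs <- function(res, out_dir) {
  ptab <- NULL
  for (p in names(res$bins)) {
    tab <- res$bins[[p]]
    col <- data.frame(tab$p_value)
    names(col) <- p
    ptab <- if (is.null(ptab)) cbind(data.frame(bin = tab$bin), col) else
      cbind(ptab, col)
  }
  write_results_csv(ptab, file.path(out_dir, "bins_pvalues.csv"))
  for (p in names(res$bins)) {
    write_results_csv(as.data.frame(res$bins[[p]]),
                      file.path(out_dir, paste0("bins_", p, ".csv")))
  }
  ax <- res$windows$body$time_axis
  write_results_csv(
    data.frame(t = ax,
               body_mean_real = res$body_curves$real$mean_deg,
               body_R_real = res$body_curves$real$R,
               body_mean_random = res$body_curves$random$mean_deg,
               body_R_random = res$body_curves$random$R,
               yaw_mean_real = res$yaw_curves$real$mean_deg,
               yaw_R_real = res$yaw_curves$real$R,
               yaw_mean_random = res$yaw_curves$random$mean_deg,
               yaw_R_random = res$yaw_curves$random$R),
    file.path(out_dir, "angle_curves.csv"))
  write_results_csv(
    data.frame(R_before_real = res$body_R$real$R_before,
               R_after_real = res$body_R$real$R_after),
    file.path(out_dir, "body_R_pairs.csv"))
  write_results_csv(
    data.frame(test = c("body_real", "body_random", "yaw_real",
                        "yaw_random"),
               p_value = c(res$body_R$real$p_value,
                           res$body_R$random$p_value,
                           res$yaw_R$real$p_value,
                           res$yaw_R$random$p_value),
               n_pairs = c(res$body_R$real$n_pairs,
                           res$body_R$random$n_pairs,
                           res$yaw_R$real$n_pairs,
                           res$yaw_R$random$n_pairs)),
    file.path(out_dir, "paired_R_tests.csv"))
  cr <- res$crossing_rate
  write_results_csv(
    data.frame(t = cr$real$t, z_mean_real = cr$real$mean,
               z_sem_real = cr$real$sem, z_mean_random = cr$random$mean,
               z_sem_random = cr$random$sem),
    file.path(out_dir, "crossing_rate_curves.csv"))
  invisible(out_dir)
}

#' Run the full pipeline
#'
#' generate (optional) -> detect -> headmotion -> kinematics -> analyze,
#' writing every intermediate artifact as CSV plus a JSON run manifest
#' (config snapshot, seed, stage timings, input/output hashes). Re-running
#' with the same inputs and seed reproduces identical outputs.
#'
#' @param config an [analysis_config()] or a path to a YAML config.
#' @param data_dir directory with existing trial CSVs; NULL to generate a
#'   synthetic cohort into `out_dir`.
#' @param out_dir output directory.
#' @param n_trials,truth,duration generation parameters (when `data_dir`
#'   is NULL).
#' @param seed master seed.
#' @param threshold optional detection-threshold override.
#' @return Invisibly, the manifest list.
#' @export
run_all <- function(config = analysis_config(), data_dir = NULL, out_dir,
                    n_trials = 30L, seed = NULL, truth = ground_truth(),
                    duration = 120, threshold = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "plume_config"))
  if (is.null(seed)) seed <- config$rng_seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  tic <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    v
  }
  input_files <- character(0)
  if (is.null(data_dir)) {
    tic("generate", stage_generate(out_dir, config, n_trials = n_trials,
                                   seed = seed, truth = truth,
                                   duration = duration))
    data_dir <- out_dir
  } else {
    input_files <- list.files(data_dir, full.names = TRUE,
                              pattern = "\\.(csv|yaml)$")
  }
  tic("detect", stage_detect(data_dir, out_dir, config,
                             threshold = threshold))
  tic("headmotion", stage_headmotion(data_dir, out_dir, config))
  tic("kinematics", stage_kinematics(data_dir, out_dir, config))
  res <- tic("analyze", stage_analyze(out_dir, out_dir, config,
                                      seed = seed + 1L))
  outputs <- list.files(out_dir, full.names = TRUE,
                        pattern = "\\.(csv|yaml)$")
  manifest <- list(
    config = unclass(config),
    seed = seed,
    stage_timings_s = timings,
    inputs = file_hash_table(input_files),
    outputs = file_hash_table(setdiff(outputs,
                                      file.path(out_dir,
                                                "run_manifest.json"))),
    n_events = res$n_events,
    n_trials = res$n_trials)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

file_hash_table <- function(files) {
  if (length(files) == 0L) return(list())
  h <- tools::md5sum(files)
  stats::setNames(as.list(unname(h)), basename(files))
}
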