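#' Analysis configuration
#'
#' Builds the configuration object that every stage of the pipeline consumes.
#' Defaults are the published analysis constants where the source analysis
#' states them (filter cutoffs, deconvolution time constants, the 5--14 Hz
#' active-search band, event separation and source-distance filters, the
#' likelihood mask, window and bin geometry) and declared package choices
#' where it does not (sampling rates, detector threshold, wavelet grid,
#' regularization).
#'
#' @param ... named overrides of any default field (see Details).
#'
#' @details Fields and units:
#' \describe{
#'   \item{fs_sensor, fs_accel}{sampling rates of the gas sensor and the
#'     accelerometer, Hz (default 100).}
#'   \item{fps_video}{video frame rate, frames/s (default 30).}
#'   \item{lp_sensor_cutoff}{sensor low-pass cutoff, Hz (default 5).}
#'   \item{lp_accel_cutoff}{accelerometer low-pass cutoff, Hz (default 20).}
#'   \item{tau_rise, tau_decay}{difference-of-exponentials kernel time
#'     constants, s (defaults 0.02 and 10).}
#'   \item{band_lo, band_hi}{active-search band edges, Hz (defaults 5, 14).}
#'   \item{event_ratio_threshold}{slope-ratio detection threshold,
#'     dimensionless (default 1.75; see [detect_events()]).}
#'   \item{slope_window}{cumulative-sum slope segment length, s (default 1).}
#'   \item{min_event_separation}{minimum onset separation kept for group
#'     data, s (default 5).}
#'   \item{min_source_distance}{minimum animal-to-port distance at onset,
#'     px (default 15).}
#'   \item{likelihood_min}{keypoints below this pose-estimator likelihood
#'     are masked (default 0.9, strict \code{<}).}
#'   \item{window_half}{peri-event window half width, s (default 5).}
#'   \item{bin_width}{statistical bin width, s (default 1).}
#'   \item{angle_mean_window}{period over which per-trajectory mean angles
#'     and resultant strengths are taken, s (default 3).}
#'   \item{random_exclusion}{half width of the exclusion zone around real
#'     onsets when drawing surrogate windows, s (default 1).}
#'   \item{head_median_window}{moving-median window for the Z-X head-height
#'     signal, s (default 1).}
#'   \item{crossing_rate_window}{rolling window for zero-crossing rates, s
#'     (default 0.5).}
#'   \item{deconv_lambda}{Tikhonov regularization of the deconvolution,
#'     relative to the kernel's peak squared gain (default 1e-10).}
#'   \item{baseline_eps_frac}{baseline offset added to the min-shifted
#'     deconvolved trace before the cumulative sum, as a fraction of its
#'     range (default 1).}
#'   \item{cwt_omega0, cwt_voices, cwt_fmin, cwt_fmax}{Morlet
#'     center-frequency parameter and frequency grid of the wavelet
#'     transform (defaults 6, 48 voices over 0.5--25 Hz).}
#'   \item{gmm_k, gmm_max_k}{mixture size used for the head-state threshold
#'     and the largest size scanned for BIC reporting (defaults 3, 5).}
#'   \item{speed_smooth_window}{boxcar smoothing of the speed trace, s
#'     (default 0.2).}
#'   \item{literal_body_vector}{if TRUE, use the backward mid-point-to-body
#'     heading vector for the body angle instead of the forward one
#'     (default FALSE; see [body_angle()]).}
#'   \item{rng_seed}{base seed for stochastic stages (default 1).}
#' }
#'
#' @return A validated list of class `plume_config`.
#' @seealso [load_config()], [save_config()]
#' @export
#' @examples
#' cfg <- analysis_config(band_lo = 5, band_hi = 14)
#' cfg$tau_decay
analysis_config <- function(...) {
  cfg <- config_defaults()
  over <- list(...)
  if (length(over) > 0L) {
    if (is.null(names(over)) || any(names(over) == "")) {
      stop("all configuration overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0L) {
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(over)] <- over
  }
  validate_config(cfg)
}

config_defaults <- function() {
  list(
    fs_sensor = 100,
    fs_accel = 100,
    fps_video = 30,
    lp_sensor_cutoff = 5,
    lp_accel_cutoff = 20,
    tau_rise = 0.02,
    tau_decay = 10,
    band_lo = 5,
    band_hi = 14,
    event_ratio_threshold = 1.75,
    slope_window = 1,
    min_event_separation = 5,
    min_source_distance = 15,
    likelihood_min = 0.9,
    window_half = 5,
    bin_width = 1,
    angle_mean_window = 3,
    random_exclusion = 1,
    head_median_window = 1,
    crossing_rate_window = 0.5,
    deconv_lambda = 1e-10,
    baseline_eps_frac = 1,
    cwt_omega0 = 6,
    cwt_voices = 48,
    cwt_fmin = 0.5,
    cwt_fmax = 25,
    gmm_k = 3,
    gmm_max_k = 5,
    speed_smooth_window = 0.2,
    literal_body_vector = FALSE,
    rng_seed = 1L
  )
}

validate_config <- function(cfg) {
  num_fields <- setdiff(names(config_defaults()), "literal_body_vector")
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("config field '", f, "' must be a single finite number",
           call. = FALSE)
    }
    cfg[[f]] <- as.numeric(v)
  }
  if (!is.logical(cfg$literal_body_vector) || length(cfg$literal_body_vector) != 1L) {
    stop("config field 'literal_body_vector' must be TRUE or FALSE", call. = FALSE)
  }
  durations <- c("tau_rise", "tau_decay", "slope_window", "min_event_separation",
                 "window_half", "bin_width", "angle_mean_window",
                 "random_exclusion", "head_median_window",
                 "crossing_rate_window", "speed_smooth_window")
  for (f in durations) {
    if (cfg[[f]] <= 0) stop("config field '", f, "' must be > 0", call. = FALSE)
  }
  for (f in c("fs_sensor", "fs_accel", "fps_video", "cwt_voices",
              "cwt_fmin", "cwt_fmax", "cwt_omega0", "gmm_k", "gmm_max_k",
              "deconv_lambda", "baseline_eps_frac", "min_source_distance")) {
    if (cfg[[f]] <= 0) stop("config field '", f, "' must be > 0", call. = FALSE)
  }
  if (cfg$tau_rise >= cfg$tau_decay) {
    stop("config field 'tau_rise' must be smaller than 'tau_decay'",
         call. = FALSE)
  }
  if (!(cfg$band_lo < cfg$band_hi)) {
    stop("config field 'band_lo' must be smaller than 'band_hi'", call. = FALSE)
  }
  if (!(cfg$band_hi < cfg$fs_accel / 2)) {
    stop("config field 'band_hi' must be below the accelerometer Nyquist ",
         "frequency (fs_accel/2)", call. = FALSE)
  }
  if (!(cfg$lp_sensor_cutoff < cfg$fs_sensor / 2)) {
    stop("config field 'lp_sensor_cutoff' must be below fs_sensor/2",
         call. = FALSE)
  }
  if (!(cfg$lp_accel_cutoff < cfg$fs_accel / 2)) {
    stop("config field 'lp_accel_cutoff' must be below fs_accel/2",
         call. = FALSE)
  }
  if (cfg$likelihood_min < 0 || cfg$likelihood_min > 1) {
    stop("config field 'likelihood_min' must lie in [0, 1]", call. = FALSE)
  }
  if (!(cfg$cwt_fmin < cfg$band_lo && cfg$band_hi < cfg$cwt_fmax)) {
    stop("wavelet frequency grid [cwt_fmin, cwt_fmax] must cover ",
         "[band_lo, band_hi]", call. = FALSE)
  }
  if (cfg$event_ratio_threshold <= 1) {
    stop("config field 'event_ratio_threshold' must be > 1", call. = FALSE)
  }
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  structure(cfg, class = "plume_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Any field omitted from the file keeps its default; unknown fields are an
#' error. An empty file yields the full default configuration.
#'
#' @param path path to a YAML file.
#' @return A `plume_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain a YAML mapping", call. = FALSE)
  do.call(analysis_config, raw)
}

#' Write an analysis configuration to a YAML file
#'
#' @param cfg a `plume_config` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "plume_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

#' @export
print.plume_config <- function(x, ...) {
  cat("<plume_config>\n")
  for (f in names(x)) cat(sprintf("  %-22s %s\n", f, format(x[[f]])))
  invisible(x)
}
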