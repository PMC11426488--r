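#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' so the pass band has unit gain, zero phase shift, and the output length
#' equals the input length.
#'
#' @param ts a [time_series()].
#' @param cutoff cutoff frequency, Hz; must be below the Nyquist frequency.
#' @param order filter order before the forward-backward pass (default 4).
#' @return A filtered `plume_ts` with the same sampling.
#' @export
lowpass <- function(ts, cutoff, order = 4L) {
  stopifnot(inherits(ts, "plume_ts"))
  if (cutoff >= ts$fs / 2) {
    stop("low-pass cutoff must be below the Nyquist frequency (fs/2)",
         call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (ts$fs / 2), type = "low")
  n <- ts_n(ts)
  # odd-reflection padding long enough for the filter transient to die out,
  # so the forward-backward pass keeps unit DC gain at the trace edges
  pad <- min(n - 1L, max(3L * order, as.integer(ceiling(10 * ts$fs / cutoff))))
  out <- ts$values
  for (j in seq_len(ncol(out))) {
    x <- ts$values[, j]
    xp <- c(2 * x[1] - x[(pad + 1L):2],
            x,
            2 * x[n] - x[(n - 1L):(n - pad)])
    yp <- signal::filtfilt(bf, xp)
    out[, j] <- yp[(pad + 1L):(pad + n)]
  }
  time_series(out, fs = ts$fs, t0 = ts$t0, channels = colnames(ts$values))
}

#' Difference-of-exponentials sensor kernel
#'
#' The metal-oxide sensor's impulse response is modeled as
#' `k(t) = exp(-t/tau_decay) - exp(-t/tau_rise)` for `t >= 0`, normalized to
#' unit area, so deconvolved amplitudes are in impulse-mass units.
#'
#' @param n number of samples to return.
#' @param fs sampling rate, Hz.
#' @param tau_rise,tau_decay time constants, s (`tau_rise < tau_decay`).
#' @return Numeric vector of length `n` (the sampled kernel).
#' @export
doe_kernel <- function(n, fs, tau_rise = 0.02, tau_decay = 10) {
  check_taus(tau_rise, tau_decay)
  t <- (seq_len(n) - 1L) / fs
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  k / (tau_decay - tau_rise)   # analytic area of the continuous kernel
}

check_taus <- function(tau_rise, tau_decay) {
  if (!(tau_rise > 0 && tau_decay > tau_rise)) {
    stop("need 0 < tau_rise < tau_decay", call. = FALSE)
  }
  invisible(TRUE)
}

# FFT length with enough zero padding to keep the circular convolution
# linear over the kernel's effective support.
deconv_fft_n <- function(n, fs, tau_decay) {
  stats::nextn(n + ceiling(6 * tau_decay * fs), 2L)
}

#' Convolve a trace with the sensor kernel
#'
#' Forward model of the sensor: the input (instantaneous odor concentration
#' in impulse-mass units) convolved with the unit-area
#' difference-of-exponentials kernel. Inverse of [deconvolve()] on noiseless
#' inputs.
#'
#' @inheritParams deconvolve
#' @return A `plume_ts` of the same length.
#' @export
convolve_kernel <- function(ts, tau_rise = 0.02, tau_decay = 10) {
  stopifnot(inherits(ts, "plume_ts"))
  check_taus(tau_rise, tau_decay)
  x <- ts$values[, 1]
  n <- length(x)
  nfft <- deconv_fft_n(n, ts$fs, tau_decay)
  k <- doe_kernel(nfft, ts$fs, tau_rise, tau_decay)
  # zeroing the kernel tail that would wrap around keeps the circular
  # product an exact linear convolution over the returned samples
  k[seq.int(nfft - n + 1L, nfft)] <- 0
  y <- Re(stats::fft(stats::fft(c(x, rep(0, nfft - n))) *
                       stats::fft(k / ts$fs), inverse = TRUE)) / nfft
  time_series(y[seq_len(n)], fs = ts$fs, t0 = ts$t0)
}

#' Deconvolve the sensor response
#'
#' Inverts the convolution with the difference-of-exponentials kernel by
#' regularized frequency-domain division (Tikhonov): the inverse filter is
#' `conj(K) / (|K|^2 + lambda * max|K|^2)`, which caps the gain applied to
#' white noise at `1 / (2 sqrt(lambda))` relative to the kernel's peak gain.
#' Re-convolving the output with the kernel recovers a noiseless input to
#' well under 1e-3 of its range at the default `lambda`.
#'
#' @param ts a single-channel [time_series()] (normally the low-passed
#'   sensor trace).
#' @param tau_rise,tau_decay kernel time constants, s.
#' @param lambda relative Tikhonov regularization (default taken from
#'   [analysis_config()]'s `deconv_lambda`).
#' @return A `plume_ts` holding the deconvolved signal.
#' @export
deconvolve <- function(ts, tau_rise = 0.02, tau_decay = 10, lambda = 1e-10) {
  stopifnot(inherits(ts, "plume_ts"))
  check_taus(tau_rise, tau_decay)
  if (lambda <= 0) stop("'lambda' must be > 0", call. = FALSE)
  x <- ts$values[, 1]
  n <- length(x)
  nfft <- deconv_fft_n(n, ts$fs, tau_decay)
  k <- doe_kernel(nfft, ts$fs, tau_rise, tau_decay)
  K <- stats::fft(k / ts$fs)
  p2 <- Mod(K)^2
  lam <- lambda * max(p2)
  # continue the trace past its end with the sensor's natural decay so the
  # padding region is consistent with zero input; a plain zero pad would
  # look like a cliff and put a large spurious transient at the trace end.
  # The last quarter second (where the zero-phase low-pass has its own end
  # transient) is replaced by the same continuation before inverting.
  guard <- max(1L, min((n - 1L) %/% 2L, as.integer(round(0.25 * ts$fs))))
  nk <- n - guard
  # a nonzero level at the first sample would otherwise be read as a step
  # from the implicit zero state before the recording; remove the starting
  # baseline, invert, and put the equivalent DC concentration back
  b <- stats::median(x[seq_len(min(n, guard))])
  xb <- x - b
  xg <- c(xb[seq_len(nk)],
          xb[nk] * exp(-(seq_len(nfft - nk)) / (ts$fs * tau_decay)))
  X <- stats::fft(xg)
  d <- Re(stats::fft(X * Conj(K) / (p2 + lam), inverse = TRUE)) / nfft
  time_series(d[seq_len(n)] + b / (1 + lam), fs = ts$fs, t0 = ts$t0)
}

#' Cumulative-sum slope ratio
#'
#' The change statistic behind event detection. The deconvolved trace is
#' shifted so its minimum is zero and offset by a baseline epsilon (a
#' configurable fraction of its range, default the full range, which makes
#' the statistic scale-free and places a unit-height event's ratio near 2).
#' Its running integral `C(t)` is then fit by least squares over a
#' 1-s segment forward of each sample and a 1-s segment backward, and the
#' ratio of forward to reverse slope is returned.
#'
#' @param deconv deconvolved trace, a `plume_ts`.
#' @param config an [analysis_config()] (uses `slope_window`,
#'   `baseline_eps_frac`, `event_ratio_threshold`).
#' @return A list with `t` (sample times), `ratio` (NA where a full window
#'   does not fit on both sides), and `eps` (the baseline offset used).
#' @export
slope_ratio <- function(deconv, config = analysis_config()) {
  stopifnot(inherits(deconv, "plume_ts"))
  x <- deconv$values[, 1]
  n <- length(x)
  fs <- deconv$fs
  nw <- max(2L, as.integer(round(config$slope_window * fs)))
  if (n <= 2L * nw) {
    stop("trace must be longer than twice the slope window", call. = FALSE)
  }
  # robust min shift and range (0.1% quantiles), so a handful of filter /
  # deconvolution edge-transient samples cannot inflate the baseline
  q <- stats::quantile(x, c(0.001, 0.999), names = FALSE, type = 7L)
  xs <- x - q[1]
  rng <- q[2] - q[1]
  eps <- config$baseline_eps_frac * (if (rng > 0) rng else 1)
  C <- cumsum(xs + eps) / fs
  dt <- 1 / fs
  j <- seq_len(nw) - 1L
  denom <- dt^2 * nw * (nw^2 - 1) / 12
  w <- (j - (nw - 1) / 2) * dt / denom
  filt <- stats::filter(C, rev(w), method = "convolution", sides = 1L)
  # filt[i + nw - 1] is the OLS slope of C over samples i .. i+nw-1
  slope_start <- as.numeric(filt)[seq(nw, n)]           # index i -> slope_start[i]
  ratio <- rep(NA_real_, n)
  idx <- seq(nw + 1L, n - nw + 1L)
  ratio[idx] <- slope_start[idx] / slope_start[idx - nw]
  list(t = ts_time(deconv), ratio = ratio, eps = eps)
}

#' Detect plume-encounter onsets
#'
#' An onset is the first sample of each maximal run where the
#' forward/reverse cumulative-sum slope ratio (see [slope_ratio()]) is at
#' or above `event_ratio_threshold`. Adding a constant to the raw trace
#' does not change the result (the deconvolution is linear and the minimum
#' shift removes DC).
#'
#' @param deconv deconvolved trace, a `plume_ts`.
#' @param config an [analysis_config()].
#' @param threshold optional override of `config$event_ratio_threshold`.
#' @return A `plume_events` data frame: `onset_s`, `ratio` (ratio at the
#'   onset sample), `distance_px` (NA until [filter_events()]), `retained`,
#'   `reason`.
#' @export
detect_events <- function(deconv, config = analysis_config(),
                          threshold = NULL) {
  sr <- slope_ratio(deconv, config)
  th <- if (is.null(threshold)) config$event_ratio_threshold else threshold
  plume_events_from_ratio(sr, th)
}

plume_events_from_ratio <- function(sr, threshold) {
  # tolerance keeps exact-equality crossings (noiseless constructions where
  # the ratio attains the threshold to rounding error) deterministic
  above <- !is.na(sr$ratio) & sr$ratio >= threshold - 1e-9 * max(1, threshold)
  starts <- which(above & !c(FALSE, above[-length(above)]))
  new_plume_events(onset_s = sr$t[starts], ratio = sr$ratio[starts])
}

new_plume_events <- function(onset_s, ratio,
                             distance_px = rep(NA_real_, length(onset_s)),
                             retained = rep(TRUE, length(onset_s)),
                             reason = rep("", length(onset_s))) {
  structure(data.frame(onset_s = as.numeric(onset_s),
                       ratio = as.numeric(ratio),
                       distance_px = as.numeric(distance_px),
                       retained = as.logical(retained),
                       reason = as.character(reason),
                       stringsAsFactors = FALSE),
            class = c("plume_events", "data.frame"))
}

#' Calibrate the detection threshold on blank sessions
#'
#' Reproduces the calibration strategy of pooling event-free recordings
#' (plume present, no animal) and choosing the smallest threshold whose
#' pooled false-positive rate does not exceed a target. Blank traces are
#' raw sensor voltages; the full low-pass + deconvolution chain is applied
#' before the slope-ratio statistic.
#'
#' @param traces list of raw single-channel blank [time_series()].
#' @param config an [analysis_config()].
#' @param target_fp_rate acceptable event rate on blanks, events/min. A
#'   target of 0 returns the maximum observed ratio plus a margin.
#' @return A list: `threshold`, `rate_at_threshold` (events/min on the
#'   calibration blanks), `max_ratio`.
#' @export
calibrate_threshold <- function(traces, config = analysis_config(),
                                target_fp_rate = 0.1) {
  if (!is.list(traces) || length(traces) < 1L) {
    stop("need at least one blank trace", call. = FALSE)
  }
  ratios <- vector("list", length(traces))
  total_min <- 0
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    filt <- lowpass(tr, config$lp_sensor_cutoff)
    dec <- deconvolve(filt, config$tau_rise, config$tau_decay,
                      config$deconv_lambda)
    sr <- slope_ratio(dec, config)
    ratios[[i]] <- sr$ratio
    total_min <- total_min + sum(!is.na(sr$ratio)) / tr$fs / 60
  }
  count_at <- function(th) {
    sum(vapply(ratios, function(r) {
      above <- !is.na(r) & r >= th
      sum(above & !c(FALSE, above[-length(above)]))
    }, numeric(1)))
  }
  max_ratio <- max(vapply(ratios, function(r) max(r, na.rm = TRUE),
                          numeric(1)))
  ceiling_th <- max_ratio + 0.05 * max(max_ratio - 1, 0.01) + 1e-9
  if (target_fp_rate <= 0) {
    return(list(threshold = ceiling_th, rate_at_threshold = 0,
                max_ratio = max_ratio))
  }
  peaks <- sort(unique(unlist(lapply(ratios, function(r) {
    r0 <- r
    r0[is.na(r0)] <- -Inf
    n <- length(r0)
    r0[which(r0 >= c(-Inf, r0[-n]) & r0 > c(r0[-1], -Inf))]
  }))))
  peaks <- peaks[peaks > 1]
  chosen <- ceiling_th
  rate_chosen <- 0
  for (th in peaks) {
    rate <- count_at(th) / total_min
    if (rate <= target_fp_rate) {
      chosen <- th
      rate_chosen <- rate
      break
    }
  }
  med_peak <- if (length(peaks) > 0L) stats::median(peaks) else 1
  if (chosen > 1 + 10 * max(med_peak - 1, 1e-6)) {
    warning("calibrated threshold is far above typical blank ratios; ",
            "the blank traces may contain real events", call. = FALSE)
  }
  list(threshold = chosen, rate_at_threshold = rate_chosen,
       max_ratio = max_ratio)
}

#' Apply the group-data event filters
#'
#' Marks onsets as rejected when (a) they fall within
#' `min_event_separation` of the previous onset kept by the separation rule
#' (first-kept policy), (b) the animal's body keypoint is within
#' `min_source_distance` pixels of the odor port at onset, or (c) the onset
#' lies closer than `window_half` to an in-arena boundary so its peri-event
#' window would not fit. The first violated rule (in that order) is
#' recorded as the reason.
#'
#' @param events a `plume_events` table from [detect_events()].
#' @param keypoints a [keypoint_track()] used for the animal's position.
#' @param port_xy odor-port position, px.
#' @param in_arena in-arena interval(s), `c(start, end)` or a matrix of rows.
#' @param config an [analysis_config()].
#' @return The events table with `distance_px`, `retained`, `reason` filled.
#' @export
filter_events <- function(events, keypoints, port_xy, in_arena,
                          config = analysis_config()) {
  stopifnot(inherits(events, "plume_events"))
  if (is.vector(in_arena)) in_arena <- matrix(in_arena, ncol = 2L, byrow = TRUE)
  n <- nrow(events)
  if (n == 0L) return(events)
  if (is.unsorted(events$onset_s)) {
    stop("event onsets must be sorted", call. = FALSE)
  }
  retained <- rep(TRUE, n)
  reason <- rep("", n)

  # (a) separation: greedy first-kept over the raw onset series
  last_kept <- -Inf
  sep_ok <- logical(n)
  for (i in seq_len(n)) {
    if (events$onset_s[i] - last_kept > config$min_event_separation) {
      sep_ok[i] <- TRUE
      last_kept <- events$onset_s[i]
    }
  }

  # (b) proximity: body keypoint at the nearest video frame
  dist_px <- rep(NA_real_, n)
  if (!is.null(keypoints)) {
    fi <- kp_index(keypoints, events$onset_s)
    bx <- keypoints$frames$body_x[fi]
    by <- keypoints$frames$body_y[fi]
    dist_px <- sqrt((bx - port_xy[1])^2 + (by - port_xy[2])^2)
  }

  # (c) edge: full peri-event window support inside the in-arena interval,
  # with one sample period of the coarsest stream as margin so that
  # nearest-sample lookup lands inside every stream at the window ends
  margin <- config$window_half +
    1 / min(config$fps_video, config$fs_sensor, config$fs_accel)
  edge_ok <- vapply(events$onset_s, function(o) {
    any(o - in_arena[, 1] >= margin & in_arena[, 2] - o >= margin)
  }, logical(1))

  for (i in seq_len(n)) {
    if (!sep_ok[i]) {
      retained[i] <- FALSE
      reason[i] <- "separation"
    } else if (!is.na(dist_px[i]) && dist_px[i] <= config$min_source_distance) {
      retained[i] <- FALSE
      reason[i] <- "proximity"
    } else if (!edge_ok[i]) {
      retained[i] <- FALSE
      reason[i] <- "edge"
    }
  }
  new_plume_events(events$onset_s, events$ratio, dist_px, retained, reason)
}

#' Retained onsets of an event table
#' @param events a `plume_events` table.
#' @return Numeric vector of retained onset times, s.
#' @export
retained_onsets <- function(events) {
  events$onset_s[events$retained]
}
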