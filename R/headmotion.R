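#' Accelerometer calibration parameters
#'
#' Zero offsets and volt-per-g scales per axis, obtained in practice by
#' holding the head piece in canonical orientations against gravity.
#'
#' @param zero_offset length-3 numeric, volts at 0 g per axis.
#' @param scale length-3 numeric, volts per g per axis (nonzero).
#' @return An object of class `accel_calibration`.
#' @export
accel_calibration <- function(zero_offset, scale) {
  if (length(zero_offset) != 3L || length(scale) != 3L) {
    stop("calibration needs 3 offsets and 3 scales", call. = FALSE)
  }
  if (any(scale == 0)) stop("calibration scale must be nonzero on all axes",
                            call. = FALSE)
  structure(list(zero_offset = as.numeric(zero_offset),
                 scale = as.numeric(scale)),
            class = "accel_calibration")
}

#' Convert accelerometer voltages to g
#'
#' `g = (volts - zero_offset) / scale`, per axis.
#'
#' @param raw 3-channel [time_series()] in volts.
#' @param cal an [accel_calibration()].
#' @return A 3-channel `plume_ts` in g.
#' @export
calibrate_accel <- function(raw, cal) {
  stopifnot(inherits(raw, "plume_ts"), inherits(cal, "accel_calibration"))
  if (ncol(raw$values) != 3L) stop("'raw' must have 3 channels", call. = FALSE)
  out <- sweep(sweep(raw$values, 2L, cal$zero_offset, "-"), 2L, cal$scale, "/")
  time_series(out, fs = raw$fs, t0 = raw$t0, channels = c("x", "y", "z"))
}

#' Jerk of the accelerometer signal
#'
#' Zero-phase low-pass (default 20 Hz cutoff) followed by the time
#' derivative (first central difference scaled by the sampling rate; the
#' first and last samples use one-sided differences). Any DC acceleration
#' component is removed by the derivative, so jerk-based band power is
#' invariant to constant offsets.
#'
#' @param accel [time_series()] in g (1 or 3 channels).
#' @param config an [analysis_config()] (uses `lp_accel_cutoff`).
#' @return A `plume_ts` in g/s with the same channels.
#' @export
jerk <- function(accel, config = analysis_config()) {
  stopifnot(inherits(accel, "plume_ts"))
  filt <- lowpass(accel, config$lp_accel_cutoff)
  v <- filt$values
  n <- nrow(v)
  if (n < 3L) stop("trace too short for a derivative", call. = FALSE)
  d <- v
  d[2:(n - 1L), ] <- (v[3:n, , drop = FALSE] - v[1:(n - 2L), , drop = FALSE]) *
    accel$fs / 2
  d[1L, ] <- (v[2L, ] - v[1L, ]) * accel$fs
  d[n, ] <- (v[n, ] - v[n - 1L, ]) * accel$fs
  time_series(d, fs = accel$fs, t0 = accel$t0, channels = colnames(v))
}

#' Continuous wavelet transform (analytic Morlet)
#'
#' FFT-based CWT with the standard analytic Morlet wavelet
#' (`psi_hat(w) = pi^(-1/4) exp(-(s w - omega0)^2 / 2)` for `w > 0`,
#' L2-normalized per scale). The scale-to-frequency conversion is
#' `f = omega0 / (2 pi s)`.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param freqs center frequencies of the analysis grid, Hz.
#' @param omega0 Morlet center-frequency parameter (default 6).
#' @return A complex matrix, `length(x)` rows by `length(freqs)` columns.
#' @export
cwt_morlet <- function(x, fs, freqs, omega0 = 6) {
  n <- length(x)
  nfft <- stats::nextn(2L * n, 2L)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  w <- 2 * pi * fs * seq(0L, nfft - 1L) / nfft
  w[w > pi * fs] <- w[w > pi * fs] - 2 * pi * fs   # wrap to (-fs/2, fs/2]
  out <- matrix(0i, nrow = n, ncol = length(freqs))
  pos <- w > 0
  for (j in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[j])
    psi <- numeric(nfft)
    psi[pos] <- pi^(-0.25) * sqrt(2 * pi * s * fs) *
      exp(-0.5 * (s * w[pos] - omega0)^2)
    W <- stats::fft(X * psi, inverse = TRUE) / nfft
    out[, j] <- W[seq_len(n)]
  }
  out
}

# log-spaced analysis grid guaranteed to cover [fmin, fmax]
cwt_freq_grid <- function(config) {
  exp(seq(log(config$cwt_fmin), log(config$cwt_fmax),
          length.out = as.integer(config$cwt_voices)))
}

#' Band power and dominant frequency of the head-pitch jerk
#'
#' Computes the CWT power (`|coefficients|^2`) of a single jerk channel on
#' a log-spaced frequency grid, the mean power over the active-search band
#' (`band_lo`--`band_hi`, default 5--14 Hz), and per sample the dominant
#' frequency, i.e. the grid frequency with the highest power within the
#' band.
#'
#' @param jerk_x single-channel [time_series()] (the gravity-aligned jerk
#'   axis).
#' @param config an [analysis_config()].
#' @return An object of class `band_power_series`: `t`, `power` (band
#'   power, arbitrary units squared), `dominant_freq` (Hz), `band`, and the
#'   full `freqs` grid.
#' @export
cwt_band_power <- function(jerk_x, config = analysis_config()) {
  stopifnot(inherits(jerk_x, "plume_ts"))
  if (ts_duration(jerk_x) < 2) {
    stop("trace must be at least 2 s long", call. = FALSE)
  }
  freqs <- cwt_freq_grid(config)
  in_band <- freqs >= config$band_lo & freqs <= config$band_hi
  if (!any(in_band)) {
    stop("active-search band is outside the wavelet frequency grid",
         call. = FALSE)
  }
  coef <- cwt_morlet(jerk_x$values[, 1], jerk_x$fs, freqs, config$cwt_omega0)
  pow <- Mod(coef)^2
  band_pow <- pow[, in_band, drop = FALSE]
  band_freqs <- freqs[in_band]
  structure(list(t = ts_time(jerk_x),
                 power = rowMeans(band_pow),
                 dominant_freq = band_freqs[max.col(band_pow, "first")],
                 band = c(config$band_lo, config$band_hi),
                 freqs = freqs),
            class = "band_power_series")
}

#' @export
print.band_power_series <- function(x, ...) {
  cat(sprintf("<band_power_series> %d samples, band %g-%g Hz\n",
              length(x$t), x$band[1], x$band[2]))
  invisible(x)
}

# centered moving median with truncated windows at the edges
movmedian <- function(x, k) {
  n <- length(x)
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  if (k <= 1L) return(x)
  half <- k %/% 2L
  out <- stats::runmed(x, k, endrule = "keep")
  for (i in seq_len(half)) {
    out[i] <- stats::median(x[seq_len(i + half)])
    out[n - i + 1L] <- stats::median(x[seq(n - i + 1L - half, n)])
  }
  as.numeric(out)
}

#' Z-minus-X head-height signal
#'
#' A 1-s centered moving median is taken of the Z and X accelerometer axes
#' and the X median is subtracted from the Z median. High values indicate
#' a raised head. Edges use truncated windows.
#'
#' @param accel 3-channel [time_series()] in g (channels x, y, z).
#' @param config an [analysis_config()] (uses `head_median_window`).
#' @return A single-channel `plume_ts` holding `d = med(Z) - med(X)`, g.
#' @export
head_height_signal <- function(accel, config = analysis_config()) {
  stopifnot(inherits(accel, "plume_ts"))
  if (ncol(accel$values) != 3L) stop("'accel' must have 3 channels",
                                     call. = FALSE)
  if (config$head_median_window > ts_duration(accel)) {
    stop("'head_median_window' exceeds the trace duration", call. = FALSE)
  }
  k <- 2L * (as.integer(round(config$head_median_window * accel$fs)) %/% 2L) + 1L
  d <- movmedian(accel$values[, 3], k) - movmedian(accel$values[, 1], k)
  time_series(d, fs = accel$fs, t0 = accel$t0, channels = "d")
}

#' Head-raised threshold from a Gaussian mixture
#'
#' Fits univariate Gaussian mixtures with 1 to `gmm_max_k` components
#' (unequal variances) to the pooled Z-minus-X head-height samples,
#' reports the BIC for each size, and uses the `gmm_k`-component model
#' (default 3, the size at which the BIC improvement saturates on real
#' data). The threshold is `mean - sd` of the component with the largest
#' mean ("raised" component); samples above it are classified head-raised.
#'
#' Fitting uses model-based EM (package mclust) initialized from an
#' evenly spaced subset of the sorted samples, which makes the result
#' deterministic and invariant to sample order.
#'
#' @param pooled_d numeric vector of head-height samples, g (>= 1000).
#' @param config an [analysis_config()].
#' @return An object of class `gmm_fit`: `weights`, `means`, `sds` (sorted
#'   by ascending mean), `k`, `bic` (named vector over the scanned sizes),
#'   and `threshold` (g).
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_head_state_threshold <- function(pooled_d, config = analysis_config()) {
  d <- as.numeric(pooled_d)
  d <- d[is.finite(d)]
  if (length(d) < 1000L) {
    stop("need at least 1000 pooled head-height samples", call. = FALSE)
  }
  if (stats::sd(d) == 0) {
    warning("degenerate head-height distribution (all samples identical); ",
            "falling back to a single component", call. = FALSE)
    return(structure(list(weights = 1, means = d[1], sds = 0, k = 1L,
                          bic = c(`1` = NA_real_), threshold = d[1]),
                     class = "gmm_fit"))
  }
  ds <- sort(d)
  n <- length(ds)
  sub <- if (n > 2000L) unique(as.integer(round(seq(1L, n, length.out = 2000L))))
         else seq_len(n)
  kmax <- as.integer(config$gmm_max_k)
  fit <- Mclust(ds, G = seq_len(kmax), modelNames = "V",
                        initialization = list(subset = sub), verbose = FALSE)
  if (is.null(fit)) stop("Gaussian mixture fit failed to converge",
                         call. = FALSE)
  bic <- fit$BIC[, "V"]
  names(bic) <- rownames(fit$BIC)
  k <- as.integer(config$gmm_k)
  fitk <- Mclust(ds, G = k, modelNames = "V",
                         initialization = list(subset = sub), verbose = FALSE)
  if (is.null(fitk)) stop("Gaussian mixture fit failed to converge for k = ",
                          k, call. = FALSE)
  mu <- as.numeric(fitk$parameters$mean)
  sdv <- sqrt(as.numeric(fitk$parameters$variance$sigmasq))
  if (length(sdv) == 1L) sdv <- rep(sdv, k)
  w <- as.numeric(fitk$parameters$pro)
  ord <- order(mu)
  mu <- mu[ord]; sdv <- sdv[ord]; w <- w[ord]
  structure(list(weights = w, means = mu, sds = sdv, k = k, bic = bic,
                 threshold = mu[k] - sdv[k]),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("<gmm_fit> k = %d, threshold = %.4f g\n", x$k, x$threshold))
  for (i in seq_len(x$k)) {
    cat(sprintf("  comp %d: w = %.3f, mean = %.4f, sd = %.4f\n",
                i, x$weights[i], x$means[i], x$sds[i]))
  }
  invisible(x)
}

#' Classify head-raised epochs
#'
#' @param d head-height signal, a single-channel `plume_ts` (see
#'   [head_height_signal()]).
#' @param threshold threshold in g (from [fit_head_state_threshold()]).
#' @return A list of class `head_state_series`: `t`, `d`, `threshold`,
#'   `raised` (logical per sample, `d > threshold`).
#' @export
classify_head_state <- function(d, threshold) {
  stopifnot(inherits(d, "plume_ts"))
  structure(list(t = ts_time(d), d = d$values[, 1],
                 threshold = as.numeric(threshold),
                 raised = d$values[, 1] > threshold),
            class = "head_state_series")
}
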