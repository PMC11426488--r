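# Shared helpers: independent oracles and small constructors used across
# the test files. Oracles deliberately use different code paths (per-sample
# least squares, direct convolution) than the implementation they check.

# greedy matching of detected onsets to ground truth within a tolerance
match_events <- function(detected, truth, tol = 0.5) {
  used <- rep(FALSE, length(detected))
  tp <- 0L
  errs <- numeric(0)
  for (o in truth) {
    d <- abs(detected - o)
    d[used] <- Inf
    if (length(d) > 0L && min(d) <= tol) {
      j <- which.min(d)
      used[j] <- TRUE
      tp <- tp + 1L
      errs <- c(errs, detected[j] - o)
    }
  }
  list(tp = tp, fp = sum(!used), fn = length(truth) - tp, errs = errs)
}

# brute-force slope-ratio oracle: per-sample ordinary least squares on the
# same offset cumulative sum, no filters, no vectorized convolution
oracle_slope_ratio <- function(x, fs, slope_window = 1, eps_frac = 1) {
  n <- length(x)
  nw <- as.integer(round(slope_window * fs))
  q <- stats::quantile(x, c(0.001, 0.999), names = FALSE, type = 7L)
  rng <- q[2] - q[1]
  eps <- eps_frac * (if (rng > 0) rng else 1)
  C <- cumsum(x - q[1] + eps) / fs
  tt <- (seq_len(nw) - 1L) / fs
  tc <- tt - mean(tt)
  den <- sum(tc^2)
  slope <- function(y) sum(tc * (y - mean(y))) / den
  r <- rep(NA_real_, n)
  for (i in seq(nw + 1L, n - nw + 1L)) {
    r[i] <- slope(C[i:(i + nw - 1L)]) / slope(C[(i - nw):(i - 1L)])
  }
  r
}

# direct (time-domain) convolution with the sampled kernel, O(n * k)
oracle_convolve <- function(x, fs, tau_rise = 0.02, tau_decay = 10,
                            k_len = length(x)) {
  k <- doe_kernel(k_len, fs, tau_rise, tau_decay)
  n <- length(x)
  y <- numeric(n)
  nz <- which(x != 0)
  for (j in nz) {
    idx <- j:n
    y[idx] <- y[idx] + x[j] * k[seq_along(idx)] / fs
  }
  y
}

# simple keypoint track builder (image coordinates)
make_track <- function(nose, neck, body, fps = 30,
                       p = rep(1, nrow(nose))) {
  keypoint_track(data.frame(
    nose_x = nose[, 1], nose_y = nose[, 2], nose_p = p,
    neck_x = neck[, 1], neck_y = neck[, 2], neck_p = p,
    body_x = body[, 1], body_y = body[, 2], body_p = p), fps = fps)
}

# circular SD (degrees) of a sample of angles
circ_sd_deg <- function(deg) {
  r <- circular_mean_R(deg)$R
  sqrt(-2 * log(r)) * 180 / pi
}
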