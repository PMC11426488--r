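#' Angle time series
#'
#' Signed angles in degrees wrapped to (-180, 180], one value per video
#' frame, with a validity flag. Invalid frames (masked keypoints or
#' degenerate geometry) carry NA.
#'
#' @param t frame times, s.
#' @param deg angles, degrees.
#' @param valid logical per frame.
#' @return An object of class `angle_series`.
#' @export
angle_series <- function(t, deg, valid = !is.na(deg)) {
  deg[!valid] <- NA_real_
  structure(list(t = as.numeric(t), deg = wrap_deg(deg),
                 valid = as.logical(valid)),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %d frames, %d valid\n",
              length(x$t), sum(x$valid)))
  invisible(x)
}

#' Wrap angles to (-180, 180]
#' @param deg angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_deg <- function(deg) {
  out <- deg - 360 * floor((deg + 180) / 360)
  out[!is.na(out) & out == -180] <- 180
  out
}

#' Mask low-likelihood keypoints
#'
#' Keypoints whose pose-estimator likelihood is strictly below
#' `likelihood_min` have their coordinates set to NA, removing those frames
#' from any computation that needs them. A likelihood exactly at the cutoff
#' is kept.
#'
#' @param track a [keypoint_track()].
#' @param likelihood_min cutoff (default 0.9).
#' @return A masked `keypoint_track`.
#' @export
mask_low_likelihood <- function(track, likelihood_min = 0.9) {
  stopifnot(inherits(track, "keypoint_track"))
  fr <- track$frames
  for (part in c("nose", "neck", "body")) {
    bad <- !is.na(fr[[paste0(part, "_p")]]) &
      fr[[paste0(part, "_p")]] < likelihood_min
    bad <- bad | is.na(fr[[paste0(part, "_p")]])
    fr[[paste0(part, "_x")]][bad] <- NA_real_
    fr[[paste0(part, "_y")]][bad] <- NA_real_
  }
  out <- track
  out$frames <- fr
  out
}

# Signed angle helpers. Keypoints are in image coordinates (y down); both
# angles are defined by their on-screen chirality, which maps to plain
# atan2 expressions of the image-frame cross product:
#   * clockwise-on-screen of v1 -> v2 positive: atan2(cross_img, dot)
#   * counter-clockwise-on-screen positive:     atan2(-cross_img, dot)
# where cross_img = v1x * v2y - v1y * v2x (the y-down frame flips the sign
# of the mathematical y-up cross product).
signed_angle_img <- function(v1x, v1y, v2x, v2y, clockwise_positive = TRUE) {
  cross <- v1x * v2y - v1y * v2x
  dot <- v1x * v2x + v1y * v2y
  s <- if (clockwise_positive) 1 else -1
  deg <- atan2(s * cross, dot) * 180 / pi
  deg[(v1x == 0 & v1y == 0) | (v2x == 0 & v2y == 0)] <- NA_real_
  deg
}

#' Body angle with respect to the odor port
#'
#' For each frame the mid-point `m` between the neck and body keypoints is
#' taken. The body angle is the signed angle between the animal's heading
#' vector and the vector from `m` to the port, positive when the heading is
#' clockwise (on screen) of the port direction. A mouse aimed straight at
#' the port reads 0 degrees.
#'
#' By default the heading vector is the forward axis `m - body` (pointing
#' from the body keypoint through the mid-point toward the head), which
#' makes the port-aimed reading 0. Setting `literal_body_vector = TRUE` in
#' the configuration uses the backward `body - m` vector instead, under
#' which a port-aimed mouse reads 180 degrees.
#'
#' @param track a (masked) [keypoint_track()].
#' @param port_xy odor-port position, px, image coordinates.
#' @param config an [analysis_config()].
#' @return An [angle_series()].
#' @export
body_angle <- function(track, port_xy, config = analysis_config()) {
  stopifnot(inherits(track, "keypoint_track"))
  fr <- track$frames
  mx <- (fr$neck_x + fr$body_x) / 2
  my <- (fr$neck_y + fr$body_y) / 2
  if (isTRUE(config$literal_body_vector)) {
    hx <- fr$body_x - mx
    hy <- fr$body_y - my
  } else {
    hx <- mx - fr$body_x
    hy <- my - fr$body_y
  }
  px <- port_xy[1] - mx
  py <- port_xy[2] - my
  deg <- signed_angle_img(px, py, hx, hy, clockwise_positive = TRUE)
  valid <- !is.na(deg)
  angle_series(kp_time(track), deg, valid)
}

#' Head-yaw angle
#'
#' Signed angle between the nose-to-neck axis and the forward body axis
#' (the 180-degree rotation of the neck-to-body vector): an egocentric
#' left head turn is positive, a right turn negative. Nose, neck and body
#' must all be valid on a frame.
#'
#' @param track a (masked) [keypoint_track()].
#' @return An [angle_series()].
#' @export
head_yaw <- function(track) {
  stopifnot(inherits(track, "keypoint_track"))
  fr <- track$frames
  headx <- fr$nose_x - fr$neck_x
  heady <- fr$nose_y - fr$neck_y
  fwdx <- fr$neck_x - fr$body_x
  fwdy <- fr$neck_y - fr$body_y
  # left-on-screen of the forward axis = counter-clockwise on screen
  deg <- signed_angle_img(fwdx, fwdy, headx, heady, clockwise_positive = FALSE)
  valid <- !is.na(deg)
  angle_series(kp_time(track), deg, valid)
}

#' Locomotion speed from the body keypoint
#'
#' Frame-to-frame displacement of the body keypoint scaled to px/s and
#' smoothed with a centered boxcar. Frames with a masked body keypoint
#' produce gaps; the smoothing ignores missing samples, so neighbors are
#' unaffected beyond the smoothing window.
#'
#' @param track a (masked) [keypoint_track()].
#' @param smoothing_window boxcar width, s (default 0.2).
#' @return A single-channel `plume_ts` in px/s (NA in gaps).
#' @export
speed <- function(track, smoothing_window = 0.2) {
  stopifnot(inherits(track, "keypoint_track"))
  fr <- track$frames
  n <- nrow(fr)
  v <- rep(NA_real_, n)
  dx <- diff(fr$body_x)
  dy <- diff(fr$body_y)
  v[-1L] <- sqrt(dx^2 + dy^2) * track$fps
  k <- max(1L, as.integer(round(smoothing_window * track$fps)))
  if (k > 1L) {
    good <- !is.na(v)
    roll <- function(z) {   # centered rolling sum, truncated at the edges
      cs <- cumsum(c(0, z))
      lo <- pmax(seq_len(n) - (k - 1L) %/% 2L, 1L)
      hi <- pmin(seq_len(n) + k %/% 2L, n)
      cs[hi + 1L] - cs[lo]
    }
    num <- roll(ifelse(good, v, 0))
    cnt <- roll(as.numeric(good))
    sm <- num / cnt
    sm[cnt == 0] <- NA_real_
    sm[!good] <- NA_real_   # a masked frame stays a gap
    v <- sm
  }
  time_series(v, fs = track$fps, t0 = 0, channels = "speed")
}

#' Zero crossings of an angle series
#'
#' A crossing is a sign change between two consecutive valid frames; an
#' exact 0 takes the sign of the following nonzero sample. Sign changes
#' across invalid gaps are not counted. Crossing times are linearly
#' interpolated between the two frames.
#'
#' @param yaw an [angle_series()].
#' @return Numeric vector of crossing times, s.
#' @export
zero_crossings <- function(yaw) {
  stopifnot(inherits(yaw, "angle_series"))
  y <- yaw$deg
  t <- yaw$t
  n <- length(y)
  if (n < 2L) return(numeric(0))
  s <- sign(y)
  # zeros adopt the next nonzero sign
  nz <- which(!is.na(s) & s == 0)
  if (length(nz) > 0L) {
    for (i in rev(nz)) {
      s[i] <- if (i < n && !is.na(s[i + 1L])) s[i + 1L] else 0
    }
  }
  i <- seq_len(n - 1L)
  ok <- yaw$valid[i] & yaw$valid[i + 1L] & !is.na(s[i]) & !is.na(s[i + 1L])
  cross <- ok & (s[i] * s[i + 1L] < 0)
  idx <- which(cross)
  if (length(idx) == 0L) return(numeric(0))
  frac <- (0 - y[idx]) / (y[idx + 1L] - y[idx])
  frac[!is.finite(frac)] <- 0
  t[idx] + frac * (t[idx + 1L] - t[idx])
}
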