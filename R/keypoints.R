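#' Keypoint track container
#'
#' Per-frame 2D coordinates and pose-estimator likelihoods for the three
#' tracked body parts (nose, neck, body). Coordinates follow the image
#' convention: origin at the top-left corner, y increasing downward. All
#' angle computations convert to a mathematical (y-up) frame internally.
#'
#' @param df data frame with columns `nose_x, nose_y, nose_p, neck_x,
#'   neck_y, neck_p, body_x, body_y, body_p`, one row per frame.
#' @param fps video frame rate, frames/s.
#' @return An object of class `keypoint_track`.
#' @export
keypoint_track <- function(df, fps) {
  needed <- kp_columns()
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop("keypoint data missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (nm in needed) {
    if (!is.numeric(df[[nm]])) {
      stop("keypoint column '", nm, "' must be numeric", call. = FALSE)
    }
  }
  p <- as.matrix(df[, c("nose_p", "neck_p", "body_p")])
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("keypoint likelihoods must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("'fps' must be a single positive number", call. = FALSE)
  }
  structure(list(fps = as.numeric(fps),
                 frames = as.data.frame(df)[needed],
                 coord_convention = "image-y-down"),
            class = "keypoint_track")
}

kp_columns <- function() {
  as.vector(t(outer(c("nose", "neck", "body"), c("x", "y", "p"), paste,
                    sep = "_")))
}

kp_n <- function(track) nrow(track$frames)

#' Frame times of a keypoint track
#' @param track a `keypoint_track`.
#' @return numeric vector, s (first frame at t = 0).
#' @export
kp_time <- function(track) (seq_len(kp_n(track)) - 1L) / track$fps

kp_index <- function(track, t) {
  i <- as.integer(round(t * track$fps)) + 1L
  pmin(pmax(i, 1L), kp_n(track))
}

#' @export
print.keypoint_track <- function(x, ...) {
  cat(sprintf("<keypoint_track> %d frames at %g fps (%s)\n",
              kp_n(x), x$fps, x$coord_convention))
  invisible(x)
}

#' Read a pose-estimator keypoint CSV
#'
#' Parses the three-row header dialect written by DeepLabCut-style pose
#' estimators: row 1 `scorer`, row 2 `bodyparts`, row 3 `coords`
#' (`x`/`y`/`likelihood`), with the first column holding the frame index.
#' The bodyparts `nose`, `neck` and `body` must each provide all three
#' coords columns.
#'
#' @param path CSV path.
#' @param fps video frame rate, frames/s.
#' @return A [keypoint_track()].
#' @export
read_keypoint_csv <- function(path, fps) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) < 3L) {
    stop("keypoint CSV must have the 3-row scorer/bodyparts/coords header",
         call. = FALSE)
  }
  labels <- tolower(trimws(as.character(raw[1, ])))
  if (!identical(labels[1], "scorer")) {
    stop("keypoint CSV row 1 must start with 'scorer'", call. = FALSE)
  }
  parts <- tolower(trimws(as.character(raw[2, ])))
  coords <- tolower(trimws(as.character(raw[3, ])))
  data <- raw[-(1:3), , drop = FALSE]
  out <- data.frame(row.names = seq_len(nrow(data)))
  for (part in c("nose", "neck", "body")) {
    for (co in c("x", "y", "likelihood")) {
      j <- which(parts == part & coords == co)
      if (length(j) != 1L) {
        stop("keypoint CSV missing '", co, "' column for bodypart '", part,
             "'", call. = FALSE)
      }
      v <- suppressWarnings(as.numeric(data[[j]]))
      bad <- which(is.na(v) & !(trimws(data[[j]]) %in% c("NA", "NaN", "nan", "")))
      if (length(bad) > 0L) {
        stop("non-numeric cell in column '", part, "/", co, "' at data row ",
             bad[1], call. = FALSE)
      }
      suffix <- if (co == "likelihood") "p" else co
      out[[paste(part, suffix, sep = "_")]] <- v
    }
  }
  keypoint_track(out, fps = fps)
}

#' Write a keypoint track in the pose-estimator CSV dialect
#'
#' Inverse of [read_keypoint_csv()]; used by the synthetic generator.
#'
#' @param track a `keypoint_track`.
#' @param path CSV path.
#' @param scorer scorer label written in the header.
#' @export
write_keypoint_csv <- function(track, path, scorer = "synthetic") {
  stopifnot(inherits(track, "keypoint_track"))
  parts <- c("nose", "neck", "body")
  header1 <- c("scorer", rep(scorer, 9L))
  header2 <- c("bodyparts", rep(parts, each = 3L))
  header3 <- c("coords", rep(c("x", "y", "likelihood"), times = 3L))
  cols <- as.vector(t(outer(parts, c("x", "y", "p"), paste, sep = "_")))
  body <- cbind(seq_len(kp_n(track)) - 1L,
                matrix(sprintf("%.17g", as.matrix(track$frames[cols])),
                       nrow = kp_n(track)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header1, collapse = ","), con)
  writeLines(paste(header2, collapse = ","), con)
  writeLines(paste(header3, collapse = ","), con)
  utils::write.table(body, con, sep = ",", col.names = FALSE,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One trial's synchronized data streams
#'
#' @param trial_id character id.
#' @param sensor gas-sensor trace, a single-channel [time_series()] (volts).
#' @param accel 3-channel accelerometer [time_series()] (volts or g).
#' @param keypoints a [keypoint_track()].
#' @param port_xy odor-port position, px (length-2, image coordinates).
#' @param arena_bounds arena rectangle `c(xmin, ymin, xmax, ymax)`, px.
#' @param in_arena matrix of in-arena intervals (rows `c(start, end)`, s),
#'   or a single `c(start, end)`.
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(trial_id, sensor, accel, keypoints, port_xy,
                         arena_bounds, in_arena) {
  stopifnot(inherits(sensor, "plume_ts"), inherits(accel, "plume_ts"),
            inherits(keypoints, "keypoint_track"))
  if (ncol(accel$values) != 3L) {
    stop("'accel' must have 3 channels", call. = FALSE)
  }
  if (length(port_xy) != 2L || !is.numeric(port_xy)) {
    stop("'port_xy' must be length-2 numeric", call. = FALSE)
  }
  if (length(arena_bounds) != 4L) {
    stop("'arena_bounds' must be c(xmin, ymin, xmax, ymax)", call. = FALSE)
  }
  if (is.vector(in_arena)) in_arena <- matrix(in_arena, ncol = 2L, byrow = TRUE)
  if (ncol(in_arena) != 2L || any(in_arena[, 2] <= in_arena[, 1])) {
    stop("'in_arena' intervals must have end > start", call. = FALSE)
  }
  if (port_xy[1] < arena_bounds[1] || port_xy[1] > arena_bounds[3] ||
      port_xy[2] < arena_bounds[2] || port_xy[2] > arena_bounds[4]) {
    stop("'port_xy' must lie inside 'arena_bounds'", call. = FALSE)
  }
  span <- function(ts) c(ts$t0, ts$t0 + ts_duration(ts))
  for (s in list(span(sensor), span(accel),
                 c(0, kp_n(keypoints) / keypoints$fps))) {
    if (s[2] <= min(in_arena[, 1]) || s[1] >= max(in_arena[, 2])) {
      stop("stream time range does not overlap the in-arena interval",
           call. = FALSE)
    }
  }
  structure(list(trial_id = as.character(trial_id), sensor = sensor,
                 accel = accel, keypoints = keypoints,
                 port_xy = as.numeric(port_xy),
                 arena_bounds = as.numeric(arena_bounds),
                 in_arena = in_arena),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> '%s': sensor %gs @%g Hz, accel %gs @%g Hz, %d frames @%g fps\n",
              x$trial_id, ts_duration(x$sensor), x$sensor$fs,
              ts_duration(x$accel), x$accel$fs, kp_n(x$keypoints),
              x$keypoints$fps))
  invisible(x)
}
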