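#' Uniformly sampled time series
#'
#' Light container for single- or multi-channel uniformly sampled signals.
#' Values are stored as an n-by-channels numeric matrix; time is implicit
#' (`t0 + (0:(n-1))/fs`).
#'
#' @param values numeric vector (one channel) or matrix (samples x channels).
#' @param fs sampling rate, Hz.
#' @param t0 time of the first sample, s.
#' @param channels optional channel names.
#' @return An object of class `plume_ts`.
#' @export
time_series <- function(values, fs, t0 = 0, channels = NULL) {
  if (is.atomic(values) && is.null(dim(values))) {
    values <- matrix(as.numeric(values), ncol = 1L)
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric vector or matrix", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a single positive number", call. = FALSE)
  }
  if (!is.null(channels)) {
    if (length(channels) != ncol(values)) {
      stop("'channels' length must match the number of columns", call. = FALSE)
    }
    colnames(values) <- channels
  }
  structure(list(t0 = as.numeric(t0), fs = as.numeric(fs), values = values),
            class = "plume_ts")
}

ts_n <- function(ts) nrow(ts$values)

#' Sample times of a time series
#' @param ts a `plume_ts`.
#' @return numeric vector of sample times, s.
#' @export
ts_time <- function(ts) ts$t0 + (seq_len(ts_n(ts)) - 1L) / ts$fs

ts_duration <- function(ts) ts_n(ts) / ts$fs

#' Nearest-sample index lookup
#'
#' Streams with different rates are aligned by time in seconds with
#' nearest-sample lookup; no resampling is performed.
#'
#' @param ts a `plume_ts`.
#' @param t times, s.
#' @param clamp if FALSE, times outside the series are NA.
#' @return integer indices into the series.
#' @export
ts_index <- function(ts, t, clamp = TRUE) {
  i <- as.integer(round((t - ts$t0) * ts$fs)) + 1L
  n <- ts_n(ts)
  if (clamp) {
    pmin(pmax(i, 1L), n)
  } else {
    i[i < 1L | i > n] <- NA_integer_
    i
  }
}

#' @export
print.plume_ts <- function(x, ...) {
  cat(sprintf("<plume_ts> %d samples x %d channel(s), fs = %g Hz, t0 = %g s\n",
              ts_n(x), ncol(x$values), x$fs, x$t0))
  invisible(x)
}

#' Write / read a time series as CSV
#'
#' One channel is written with header `t,value`; three channels with
#' `t,x,y,z`. The reader checks sampling uniformity (jitter beyond 1e-6 s
#' is an error) and round-trips values to better than 1e-9.
#'
#' @param ts a `plume_ts`.
#' @param path CSV path.
#' @return `path` (writer, invisibly) or a `plume_ts` (reader).
#' @export
write_timeseries_csv <- function(ts, path) {
  stopifnot(inherits(ts, "plume_ts"))
  nc <- ncol(ts$values)
  header <- if (nc == 1L) c("t", "value") else if (nc == 3L) {
    c("t", "x", "y", "z")
  } else {
    c("t", paste0("ch", seq_len(nc)))
  }
  df <- data.frame(t = ts_time(ts))
  for (j in seq_len(nc)) df[[header[j + 1L]]] <- ts$values[, j]
  names(df) <- header
  write_csv_full_precision(df, path)
  invisible(path)
}

#' @rdname write_timeseries_csv
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"t" %in% names(df)) stop("time-series CSV must have a 't' column", call. = FALSE)
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) {
      stop("non-numeric values in column '", nm, "'", call. = FALSE)
    }
  }
  t <- df$t
  n <- length(t)
  if (n < 2L) stop("time-series CSV needs at least two samples", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("column 't' must be strictly increasing", call. = FALSE)
  dt0 <- (t[n] - t[1]) / (n - 1L)
  if (max(abs(dt - dt0)) > 1e-6) {
    stop("column 't' is not uniformly sampled (jitter exceeds 1e-6 s)",
         call. = FALSE)
  }
  vals <- as.matrix(df[, setdiff(names(df), "t"), drop = FALSE])
  time_series(vals, fs = 1 / dt0, t0 = t[1],
              channels = colnames(vals))
}

# Full-precision CSV writer shared by all output stages: 17 significant
# digits guarantees exact double round trips through read.csv.
write_csv_full_precision <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- sprintf("%.17g", out[[nm]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a detected-event table as CSV
#'
#' Columns: `onset_s, ratio, distance_px, retained, reason`.
#'
#' @param events a `plume_events` object (see [detect_events()]).
#' @param path CSV path.
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "plume_events"))
  write_csv_full_precision(as.data.frame(events), path)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  needed <- c("onset_s", "ratio", "distance_px", "retained", "reason")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop("events CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$retained <- as.logical(df$retained)
  df$reason <- as.character(df$reason)
  structure(df[needed], class = c("plume_events", "data.frame"))
}

#' Write a generic results table as CSV
#'
#' Thin wrapper that writes any results data frame (per-bin statistics,
#' mean curves, paired resultant strengths) at full precision.
#'
#' @param df a data frame.
#' @param path CSV path.
#' @export
write_results_csv <- function(df, path) {
  stopifnot(is.data.frame(df))
  write_csv_full_precision(df, path)
  invisible(path)
}
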