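#' @name peri_event
#' @title Peri-event window containers
#' @description Real peri-encounter windows are the series re-aligned to
#'   each retained onset over `[-window_half, +window_half]`; random
#'   (surrogate) windows are aligned to uniformly drawn in-arena times that
#'   avoid the 1-s exclusion zone around real onsets. Both share one time
#'   axis; rows are trajectories.
NULL

series_info <- function(series) {
  if (inherits(series, "plume_ts")) {
    list(t0 = series$t0, fs = series$fs, n = ts_n(series),
         values = series$values[, 1], angle = FALSE)
  } else if (inherits(series, "angle_series")) {
    n <- length(series$t)
    fs <- if (n > 1L) (n - 1L) / (series$t[n] - series$t[1]) else 1
    list(t0 = series$t[1], fs = fs, n = n, values = series$deg, angle = TRUE)
  } else {
    stop("'series' must be a plume_ts or an angle_series", call. = FALSE)
  }
}

window_axis <- function(fs, window_half) {
  k <- as.integer(round(window_half * fs))
  seq(-k, k) / fs
}

series_window_matrix <- function(info, onsets, axis) {
  m <- matrix(NA_real_, nrow = length(onsets), ncol = length(axis))
  for (i in seq_along(onsets)) {
    idx <- as.integer(round((onsets[i] + axis - info$t0) * info$fs)) + 1L
    if (any(idx < 1L | idx > info$n)) {
      stop("event at ", format(onsets[i]),
           " s is too close to the recording edge for a full window",
           call. = FALSE)
    }
    m[i, ] <- info$values[idx]
  }
  m
}

#' Extract real peri-event windows
#'
#' One row per retained event; the series is sampled on the common time
#' axis by nearest-sample lookup. An event without full window support in
#' the series is a hard error (such events should have been rejected by
#' [filter_events()]).
#'
#' @param series a [time_series()] or [angle_series()].
#' @param events a `plume_events` table (only retained events are used).
#' @param config an [analysis_config()].
#' @return An object of class `peri_event_set` with the `real` matrix
#'   filled, `random` empty, and `sort_key` holding the animal-to-source
#'   distance at onset (for display ordering).
#' @export
extract_real_windows <- function(series, events, config = analysis_config()) {
  stopifnot(inherits(events, "plume_events"))
  info <- series_info(series)
  axis <- window_axis(info$fs, config$window_half)
  keep <- events$retained
  onsets <- events$onset_s[keep]
  structure(list(time_axis = axis,
                 real = series_window_matrix(info, onsets, axis),
                 random = matrix(NA_real_, 0L, length(axis)),
                 onsets_real = onsets,
                 onsets_random = numeric(0),
                 sort_key = events$distance_px[keep],
                 is_angle = info$angle),
            class = "peri_event_set")
}

#' Draw surrogate onset times
#'
#' The onset-time sampler behind [sample_random_windows()], exposed so that
#' one set of surrogate windows per trial can be shared across all series
#' (which keeps each animal's contribution to the real and random
#' distributions matched).
#'
#' @inheritParams sample_random_windows
#' @param support optional `c(start, end)` limiting the admissible times to
#'   the series' own support.
#' @return Sorted surrogate onset times, s.
#' @export
sample_random_onsets <- function(events, in_arena,
                                 config = analysis_config(), seed = 1L,
                                 n_draw = NULL, support = NULL) {
  stopifnot(inherits(events, "plume_events"))
  if (is.vector(in_arena)) in_arena <- matrix(in_arena, ncol = 2L, byrow = TRUE)
  if (is.null(n_draw)) n_draw <- sum(events$retained)
  # one sample period of the coarsest stream as margin (see filter_events)
  margin <- config$window_half +
    1 / min(config$fps_video, config$fs_sensor, config$fs_accel)
  supp <- cbind(in_arena[, 1] + margin, in_arena[, 2] - margin)
  if (!is.null(support)) {
    supp <- cbind(pmax(supp[, 1], support[1]), pmin(supp[, 2], support[2]))
  }
  supp <- supp[supp[, 2] > supp[, 1], , drop = FALSE]
  if (nrow(supp) == 0L) {
    stop("in-arena interval is too short to admit a surrogate window",
         call. = FALSE)
  }
  excl <- cbind(events$onset_s - config$random_exclusion,
                events$onset_s + config$random_exclusion)
  adm <- subtract_intervals(supp, excl)
  if (nrow(adm) == 0L || sum(adm[, 2] - adm[, 1]) <= 0) {
    stop("no admissible surrogate onset times remain after exclusions",
         call. = FALSE)
  }
  sort(with_seed(seed, sample_uniform_intervals(adm, n_draw)))
}

#' Extract windows at given onset times
#'
#' @inheritParams extract_real_windows
#' @param times window centers, s.
#' @param role `"real"` or `"random"`: which slot of the returned set the
#'   windows fill.
#' @return A `peri_event_set`.
#' @export
windows_at <- function(series, times, config = analysis_config(),
                       role = c("random", "real")) {
  role <- match.arg(role)
  info <- series_info(series)
  axis <- window_axis(info$fs, config$window_half)
  m <- series_window_matrix(info, times, axis)
  empty <- matrix(NA_real_, 0L, length(axis))
  out <- list(time_axis = axis,
              real = if (role == "real") m else empty,
              random = if (role == "random") m else empty,
              onsets_real = if (role == "real") times else numeric(0),
              onsets_random = if (role == "random") times else numeric(0),
              sort_key = numeric(0),
              is_angle = info$angle)
  structure(out, class = "peri_event_set")
}

#' Draw surrogate (random) peri-event windows
#'
#' Draws as many surrogate `t = 0` points as there are retained real events
#' in this trial, uniformly from the in-arena times that (a) admit a full
#' window and (b) are not within `random_exclusion` seconds of any real
#' onset. Real onsets may still fall elsewhere inside a surrogate window.
#' Deterministic given `seed`.
#'
#' @inheritParams extract_real_windows
#' @param in_arena in-arena interval(s), `c(start, end)` or rows of a matrix.
#' @param seed integer seed.
#' @param n_draw optional surrogate count override (default: one per
#'   retained real event).
#' @return A `peri_event_set` with only the `random` matrix filled.
#' @export
sample_random_windows <- function(series, events, in_arena,
                                  config = analysis_config(), seed = 1L,
                                  n_draw = NULL) {
  info <- series_info(series)
  draws <- sample_random_onsets(events, in_arena, config, seed, n_draw,
                                support = c(info$t0,
                                            info$t0 + (info$n - 1L) / info$fs))
  windows_at(series, draws, config, role = "random")
}

#' Combine real and random window sets
#'
#' @param real,random `peri_event_set`s from [extract_real_windows()] and
#'   [sample_random_windows()] over the same series.
#' @return A merged `peri_event_set`.
#' @export
peri_event_set <- function(real, random) {
  stopifnot(inherits(real, "peri_event_set"),
            inherits(random, "peri_event_set"))
  if (length(real$time_axis) != length(random$time_axis)) {
    stop("real and random sets must share a time axis", call. = FALSE)
  }
  out <- real
  out$random <- random$random
  out$onsets_random <- random$onsets_random
  out
}

#' Append the rows of several peri-event sets (across trials)
#' @param sets list of `peri_event_set`s sharing a time axis.
#' @return A pooled `peri_event_set`.
#' @export
pool_peri_event_sets <- function(sets) {
  stopifnot(length(sets) > 0L)
  out <- sets[[1L]]
  if (length(sets) > 1L) {
    out$real <- do.call(rbind, lapply(sets, `[[`, "real"))
    out$random <- do.call(rbind, lapply(sets, `[[`, "random"))
    out$onsets_real <- unlist(lapply(sets, `[[`, "onsets_real"))
    out$onsets_random <- unlist(lapply(sets, `[[`, "onsets_random"))
    out$sort_key <- unlist(lapply(sets, `[[`, "sort_key"))
  }
  out
}

#' @export
print.peri_event_set <- function(x, ...) {
  cat(sprintf("<peri_event_set> %d real + %d random rows, axis %g..%g s%s\n",
              nrow(x$real), nrow(x$random), min(x$time_axis),
              max(x$time_axis), if (x$is_angle) " (angular)" else ""))
  invisible(x)
}

# ---- interval helpers ------------------------------------------------------

subtract_intervals <- function(base, cuts) {
  if (is.null(cuts) || nrow(cuts) == 0L) return(base)
  pieces <- list()
  for (r in seq_len(nrow(base))) {
    segs <- matrix(base[r, ], ncol = 2L)
    for (cc in seq_len(nrow(cuts))) {
      nxt <- list()
      for (s in seq_len(nrow(segs))) {
        a <- segs[s, 1]; b <- segs[s, 2]
        lo <- cuts[cc, 1]; hi <- cuts[cc, 2]
        if (hi <= a || lo >= b) {
          nxt[[length(nxt) + 1L]] <- c(a, b)
        } else {
          if (lo > a) nxt[[length(nxt) + 1L]] <- c(a, lo)
          if (hi < b) nxt[[length(nxt) + 1L]] <- c(hi, b)
        }
      }
      segs <- if (length(nxt) > 0L) do.call(rbind, nxt) else
        matrix(numeric(0), ncol = 2L)
      if (nrow(segs) == 0L) break
    }
    if (nrow(segs) > 0L) pieces[[length(pieces) + 1L]] <- segs
  }
  if (length(pieces) == 0L) return(matrix(numeric(0), ncol = 2L))
  do.call(rbind, pieces)
}

sample_uniform_intervals <- function(intervals, n) {
  len <- intervals[, 2] - intervals[, 1]
  total <- sum(len)
  u <- stats::runif(n) * total
  cum <- cumsum(len)
  idx <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(len))
  intervals[idx, 1] + (u - c(0, cum)[idx])
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# ---- binned statistics -----------------------------------------------------

bin_edges <- function(window_half, bin_width) {
  if (abs((2 * window_half / bin_width) %% 1) > 1e-9) {
    stop("'bin_width' must divide the full window length", call. = FALSE)
  }
  seq(-window_half, window_half, by = bin_width)
}

#' Per-trajectory means within 1-s bins
#'
#' Means of each row of a peri-event window matrix within half-open bins
#' `[edge, edge + bin_width)` tiling the window. Missing samples are
#' excluded from a bin's mean; an all-missing bin is NA. Angular windows
#' use the circular mean.
#'
#' @param windows a `peri_event_set`.
#' @param which `"real"` or `"random"`.
#' @param config an [analysis_config()].
#' @return A rows-by-bins numeric matrix; bin labels as column names.
#' @export
bin_means <- function(windows, which = c("real", "random"),
                      config = analysis_config()) {
  which <- match.arg(which)
  m <- windows[[which]]
  edges <- bin_edges(config$window_half, config$bin_width)
  nb <- length(edges) - 1L
  bin_of <- findInterval(windows$time_axis, edges, rightmost.closed = FALSE)
  bin_of[windows$time_axis >= edges[nb + 1L]] <- NA_integer_  # t = +window_half
  bin_of[bin_of < 1L] <- NA_integer_
  out <- matrix(NA_real_, nrow = nrow(m), ncol = nb)
  colnames(out) <- sprintf("%g to %g", edges[-(nb + 1L)], edges[-1L])
  for (b in seq_len(nb)) {
    cols <- which(!is.na(bin_of) & bin_of == b)
    if (length(cols) == 0L) next
    sub <- m[, cols, drop = FALSE]
    if (windows$is_angle) {
      rad <- sub * pi / 180
      s <- rowMeans(sin(rad), na.rm = TRUE)
      c_ <- rowMeans(cos(rad), na.rm = TRUE)
      v <- atan2(s, c_) * 180 / pi
      v[rowSums(!is.na(sub)) == 0L] <- NA_real_
      out[, b] <- v
    } else {
      v <- rowMeans(sub, na.rm = TRUE)
      v[rowSums(!is.na(sub)) == 0L] <- NA_real_
      out[, b] <- v
    }
  }
  out
}

#' Per-bin Kolmogorov-Smirnov comparison of real vs random trajectories
#'
#' Two-sample KS test of the per-trajectory bin means, one test per bin,
#' reproducing the layout of the published statistics table (raw per-bin
#' probabilities, no multiple-testing correction). Bins with fewer than 5
#' values on either side are flagged and carry NA statistics.
#'
#' @param real_means,random_means rows-by-bins matrices from [bin_means()].
#' @param method `"auto"` (default: the exact two-sample distribution when
#'   the product of the group sizes is below 10000 and there are no ties,
#'   otherwise asymptotic --- the asymptotic approximation is visibly
#'   conservative at the few dozen trajectories per side typical here),
#'   `"asymptotic"`, or `"permutation"` (re-randomizes group labels
#'   `n_perm` times; exact under exchangeability, used as an independent
#'   check of the distributional tests).
#' @param n_perm permutation count.
#' @return A data frame of class `bin_comparison`: `bin`, `bin_lo`,
#'   `bin_hi`, `n_real`, `n_random`, `real_mean`, `random_mean`,
#'   `ks_stat`, `p_value`, `insufficient`.
#' @export
ks_per_bin <- function(real_means, random_means,
                       method = c("auto", "asymptotic", "permutation"),
                       n_perm = 1000L) {
  method <- match.arg(method)
  stopifnot(ncol(real_means) == ncol(random_means))
  nb <- ncol(real_means)
  labs <- colnames(real_means)
  lohi <- do.call(rbind, lapply(strsplit(labs, " to "), as.numeric))
  out <- data.frame(bin = labs, bin_lo = lohi[, 1], bin_hi = lohi[, 2],
                    n_real = NA_integer_, n_random = NA_integer_,
                    real_mean = NA_real_, random_mean = NA_real_,
                    ks_stat = NA_real_, p_value = NA_real_,
                    insufficient = FALSE, stringsAsFactors = FALSE)
  for (b in seq_len(nb)) {
    x <- real_means[, b]; x <- x[!is.na(x)]
    y <- random_means[, b]; y <- y[!is.na(y)]
    out$n_real[b] <- length(x)
    out$n_random[b] <- length(y)
    out$real_mean[b] <- if (length(x) > 0L) mean(x) else NA_real_
    out$random_mean[b] <- if (length(y) > 0L) mean(y) else NA_real_
    if (length(x) < 5L || length(y) < 5L) {
      out$insufficient[b] <- TRUE
      next
    }
    if (method %in% c("auto", "asymptotic")) {
      kt <- suppressWarnings(stats::ks.test(x, y,
        exact = if (method == "asymptotic") FALSE else NULL))
      out$ks_stat[b] <- unname(kt$statistic)
      out$p_value[b] <- kt$p.value
    } else {
      obs <- ks_stat_two(x, y)
      pooled <- c(x, y)
      nx <- length(x)
      cnt <- 0L
      for (r in seq_len(n_perm)) {
        pi_ <- sample.int(length(pooled))
        if (ks_stat_two(pooled[pi_[seq_len(nx)]],
                        pooled[pi_[-seq_len(nx)]]) >= obs - 1e-12) {
          cnt <- cnt + 1L
        }
      }
      out$ks_stat[b] <- obs
      out$p_value[b] <- (cnt + 1L) / (n_perm + 1L)
    }
  }
  class(out) <- c("bin_comparison", "data.frame")
  out
}

ks_stat_two <- function(x, y) {
  allv <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(allv)
  Fy <- stats::ecdf(y)(allv)
  max(abs(Fx - Fy))
}

# ---- circular statistics ---------------------------------------------------

#' Circular mean and resultant-vector strength
#'
#' The mean direction is the angle of the mean unit vector; the resultant
#' strength R is its length (1 = all angles identical, 0 = balanced
#' dispersion). R is invariant to adding a constant to all angles.
#'
#' @param deg angles, degrees (NAs dropped).
#' @return A list: `mean_deg`, `R`, `n`.
#' @export
circular_mean_R <- function(deg) {
  deg <- deg[!is.na(deg)]
  if (length(deg) < 1L) stop("need at least one valid angle", call. = FALSE)
  rad <- deg * pi / 180
  s <- mean(sin(rad))
  c_ <- mean(cos(rad))
  list(mean_deg = wrap_deg(atan2(s, c_) * 180 / pi),
       R = sqrt(s^2 + c_^2),
       n = length(deg))
}

#' Per-time-point circular summary of an angular window set
#'
#' @param m rows-by-time matrix of angles, degrees.
#' @return A data frame: `mean_deg` and `R` per column.
#' @export
circular_summary_columns <- function(m) {
  rad <- m * pi / 180
  s <- colMeans(sin(rad), na.rm = TRUE)
  c_ <- colMeans(cos(rad), na.rm = TRUE)
  data.frame(mean_deg = wrap_deg(atan2(s, c_) * 180 / pi),
             R = sqrt(s^2 + c_^2))
}

row_period_stats <- function(windows, which, config) {
  m <- windows[[which]]
  w <- config$angle_mean_window
  pre <- windows$time_axis >= -w & windows$time_axis < 0
  post <- windows$time_axis >= 0 & windows$time_axis < w
  stat_one <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(c(NA_real_, NA_real_))
    rad <- v * pi / 180
    s <- mean(sin(rad)); c_ <- mean(cos(rad))
    c(wrap_deg(atan2(s, c_) * 180 / pi), sqrt(s^2 + c_^2))
  }
  pre_stats <- t(apply(m[, pre, drop = FALSE], 1L, stat_one))
  post_stats <- t(apply(m[, post, drop = FALSE], 1L, stat_one))
  list(mean_before = pre_stats[, 1], R_before = pre_stats[, 2],
       mean_after = post_stats[, 1], R_after = post_stats[, 2],
       pre_cols = pre, post_cols = post)
}

#' Angular deviations from the per-period mean angle
#'
#' For each trajectory the circular mean angle is computed over the
#' `angle_mean_window` seconds before and after the onset, and the wrapped
#' differences between instantaneous angles and their period mean are
#' pooled across trajectories into `before` and `after` deviation
#' distributions. Rows with an all-invalid period are skipped.
#'
#' @param windows an angular `peri_event_set`.
#' @param which `"real"` or `"random"`.
#' @param config an [analysis_config()].
#' @return A list: `before`, `after` (pooled deviations, degrees),
#'   `n_rows_used`.
#' @export
angle_deviation_distributions <- function(windows,
                                          which = c("real", "random"),
                                          config = analysis_config()) {
  which <- match.arg(which)
  if (!windows$is_angle) stop("windows must be angular", call. = FALSE)
  st <- row_period_stats(windows, which, config)
  m <- windows[[which]]
  ok <- !is.na(st$mean_before) & !is.na(st$mean_after)
  before <- list(); after <- list()
  for (i in which(ok)) {
    before[[length(before) + 1L]] <-
      wrap_deg(m[i, st$pre_cols] - st$mean_before[i])
    after[[length(after) + 1L]] <-
      wrap_deg(m[i, st$post_cols] - st$mean_after[i])
  }
  list(before = as.numeric(stats::na.omit(unlist(before))),
       after = as.numeric(stats::na.omit(unlist(after))),
       n_rows_used = sum(ok))
}

#' Paired Wilcoxon test on before/after resultant strengths
#'
#' For each trajectory the resultant strength R of the angles is computed
#' over the `angle_mean_window` seconds before and after the onset; the
#' pairs are compared with the paired Wilcoxon signed-rank test (exact for
#' 25 or fewer informative pairs, normal approximation with continuity
#' correction above). Identical pairs throughout yield p = 1 (reported as
#' no effect).
#'
#' @inheritParams angle_deviation_distributions
#' @return A list: `p_value`, `statistic`, `n_pairs`, `R_before`,
#'   `R_after`, `median_diff` (after - before).
#' @export
paired_R_test <- function(windows, which = c("real", "random"),
                          config = analysis_config()) {
  which <- match.arg(which)
  if (!windows$is_angle) stop("windows must be angular", call. = FALSE)
  st <- row_period_stats(windows, which, config)
  ok <- !is.na(st$R_before) & !is.na(st$R_after)
  if (sum(ok) < 6L) stop("need at least 6 trajectories with both periods",
                         call. = FALSE)
  rb <- st$R_before[ok]
  ra <- st$R_after[ok]
  d <- ra - rb
  if (all(d == 0)) {
    return(list(p_value = 1, statistic = NA_real_, n_pairs = length(d),
                R_before = rb, R_after = ra, median_diff = 0))
  }
  n_inf <- sum(d != 0)
  wt <- suppressWarnings(stats::wilcox.test(ra, rb, paired = TRUE,
                                            exact = n_inf <= 25L,
                                            correct = TRUE))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       n_pairs = length(d), R_before = rb, R_after = ra,
       median_diff = stats::median(d))
}

# ---- zero-crossing rates ---------------------------------------------------

#' Z-scored rolling zero-crossing rates
#'
#' Each trajectory's crossing times (relative to its onset) are turned into
#' a rolling rate (crossings per second within a centered
#' `crossing_rate_window`), z-scored against that trajectory's own mean and
#' SD across the full window, and averaged across trajectories. Rows with
#' zero or constant-rate crossings have an undefined z-score and are
#' excluded (their count is reported).
#'
#' @param crossings list of numeric vectors, one per trajectory, crossing
#'   times relative to onset, s.
#' @param config an [analysis_config()].
#' @param grid_dt evaluation grid step, s.
#' @return A list: `t`, `mean`, `sem`, `n_used`, `n_excluded`.
#' @export
zscored_crossing_rate <- function(crossings, config = analysis_config(),
                                  grid_dt = 0.05) {
  rows <- crossing_rate_rows(crossings, config, grid_dt)
  tg <- rows$t
  if (nrow(rows$z) == 0L) {
    return(list(t = tg, mean = rep(NA_real_, length(tg)),
                sem = rep(NA_real_, length(tg)), n_used = 0L,
                n_excluded = rows$n_excluded))
  }
  list(t = tg, mean = colMeans(rows$z),
       sem = apply(rows$z, 2L, stats::sd) / sqrt(nrow(rows$z)),
       n_used = nrow(rows$z), n_excluded = rows$n_excluded)
}

#' Per-trajectory z-scored rolling crossing-rate curves
#'
#' The per-row building block of [zscored_crossing_rate()], also used to
#' feed the binned per-trajectory comparison.
#'
#' @inheritParams zscored_crossing_rate
#' @return A list: `t` (grid), `z` (rows-by-grid matrix of z-scored rates),
#'   `n_excluded` (rows with undefined z-scores).
#' @export
crossing_rate_rows <- function(crossings, config = analysis_config(),
                               grid_dt = 0.05) {
  wh <- config$window_half
  w <- config$crossing_rate_window
  tg <- seq(-wh, wh, by = grid_dt)
  # near the window edges the rolling window is truncated to the observed
  # span; dividing by the actual overlap keeps the rate unbiased there
  overlap <- pmin(tg + w / 2, wh) - pmax(tg - w / 2, -wh)
  zrows <- list()
  n_excluded <- 0L
  for (cr in crossings) {
    cr <- cr[cr >= -wh & cr <= wh]
    counts <- vapply(tg, function(t0) {
      sum(cr >= t0 - w / 2 & cr < t0 + w / 2)
    }, numeric(1))
    rate <- counts / overlap
    s <- stats::sd(rate)
    if (!is.finite(s) || s == 0) {
      n_excluded <- n_excluded + 1L
      next
    }
    zrows[[length(zrows) + 1L]] <- (rate - mean(rate)) / s
  }
  z <- if (length(zrows) > 0L) do.call(rbind, zrows) else
    matrix(numeric(0), ncol = length(tg))
  list(t = tg, z = z, n_excluded = n_excluded)
}

#' Bin means of arbitrary aligned curves
#'
#' Utility mirroring [bin_means()] for matrices that are not part of a
#' `peri_event_set` (e.g. z-scored crossing-rate curves on their own grid).
#'
#' @param m rows-by-time matrix.
#' @param t time axis, s.
#' @param config an [analysis_config()].
#' @return Rows-by-bins matrix with bin labels.
#' @export
bin_means_matrix <- function(m, t, config = analysis_config()) {
  edges <- bin_edges(config$window_half, config$bin_width)
  nb <- length(edges) - 1L
  bin_of <- findInterval(t, edges, rightmost.closed = FALSE)
  bin_of[t >= edges[nb + 1L]] <- NA_integer_
  bin_of[bin_of < 1L] <- NA_integer_
  out <- matrix(NA_real_, nrow = nrow(m), ncol = nb)
  colnames(out) <- sprintf("%g to %g", edges[-(nb + 1L)], edges[-1L])
  for (b in seq_len(nb)) {
    cols <- which(!is.na(bin_of) & bin_of == b)
    if (length(cols) == 0L) next
    v <- rowMeans(m[, cols, drop = FALSE], na.rm = TRUE)
    v[rowSums(!is.na(m[, cols, drop = FALSE])) == 0L] <- NA_real_
    out[, b] <- v
  }
  out
}
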