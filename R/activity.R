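#' Construct an activity trace
#'
#' A per-fly 1-D position time series on a uniform grid. Only positions are
#' stored; times are implied by `t0` and `frame_rate`, and speed is derived
#' with [compute_speed()].
#'
#' @param x Positions along the tube (mm).
#' @param frame_rate Sampling rate (Hz).
#' @param fly_id Identifier.
#' @param t0 Time of the first sample (s); ZT0 corresponds to t = 0 modulo
#'   24 h.
#' @param tube_length Tube length (mm); positions must lie in
#'   `[0, tube_length]`.
#' @return An `activity_trace` object.
#' @export
activity_trace <- function(x, frame_rate = 1, fly_id = 1L, t0 = 0,
                           tube_length = 65) {
  if (length(x) < 2) stop_format("activity trace needs >= 2 samples")
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop_format("frame_rate must be > 0")
  }
  if (any(x < -1e-9) || any(x > tube_length + 1e-9)) {
    stop_format("positions must lie in [0, tube_length]")
  }
  structure(list(fly_id = fly_id, x = as.numeric(x),
                 frame_rate = frame_rate, t0 = t0,
                 tube_length = tube_length),
            class = "activity_trace")
}

#' Build an activity trace from a (t, x) data frame
#'
#' Checks that the time grid is uniform (within a small tolerance) before
#' discarding it in favour of `t0` plus the inferred frame rate.
#'
#' @param df Data frame with columns `t_s` and `x_mm` (optionally `fly_id`).
#' @param fly_id Identifier, defaults to the table's `fly_id` if present.
#' @param tube_length Tube length (mm).
#' @return An `activity_trace`.
#' @export
as_activity_trace <- function(df, fly_id = NULL, tube_length = 65) {
  if (!all(c("t_s", "x_mm") %in% names(df))) {
    stop_format("need columns t_s and x_mm")
  }
  dt <- diff(df$t_s)
  if (length(dt) == 0 || any(dt <= 0) ||
      max(abs(dt - dt[1])) > 1e-6 * max(dt[1], 1)) {
    stop_format("time grid must be strictly increasing and uniform")
  }
  activity_trace(df$x_mm, frame_rate = 1 / dt[1],
                 fly_id = fly_id %||% df$fly_id[1] %||% 1L,
                 t0 = df$t_s[1], tube_length = tube_length)
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf("<activity_trace> fly %s: %d frames @ %g Hz (%.2f h)%s\n",
              x$fly_id, length(x$x), x$frame_rate,
              length(x$x) / x$frame_rate / 3600,
              if (is.null(x$speed)) "" else ", speed computed"))
  invisible(x)
}

#' Derive per-frame speed from positions
#'
#' `speed[i] = |x[i] - x[i-1]| * frame_rate` (mm/s), with `speed[1] = 0`.
#'
#' @param trace An `activity_trace`.
#' @return The trace with a `speed` element added.
#' @export
compute_speed <- function(trace) {
  stopifnot(inherits(trace, "activity_trace"))
  trace$speed <- c(0, abs(diff(trace$x)) * trace$frame_rate)
  trace
}

#' Detect sleep bouts as sustained immobility
#'
#' A sleep bout is a maximal run of frames with speed at or below
#' `immobility_eps` lasting at least `min_bout_s` (the standard 5-minute fly
#' sleep criterion). Runs are maximal: extending either end reaches a
#' supra-threshold frame or the trace boundary.
#'
#' @param trace An `activity_trace` (speed computed on demand).
#' @param immobility_eps Movement floor in mm/s; at-or-below counts as
#'   immobile.
#' @param min_bout_s Minimum bout duration (s), default 300.
#' @return Data frame of class `sleep_bouts` with `fly_id`, `start_s`,
#'   `end_s` (end exclusive; duration = `end_s - start_s`).
#' @export
detect_sleep_bouts <- function(trace, immobility_eps = 0.5, min_bout_s = 300) {
  stopifnot(inherits(trace, "activity_trace"))
  if (length(trace$x) == 0) stop_format("empty trace")
  if (is.null(trace$speed)) trace <- compute_speed(trace)
  fr <- trace$frame_rate
  r <- rle(trace$speed <= immobility_eps)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths / fr >= min_bout_s)
  out <- data.frame(
    fly_id = rep(trace$fly_id, sum(keep)),
    start_s = trace$t0 + (starts[keep] - 1L) / fr,
    end_s = trace$t0 + ends[keep] / fr
  )
  class(out) <- c("sleep_bouts", "data.frame")
  out
}

#' Total overlap of an interval with a set of (merged) intervals.
#' @noRd
interval_overlap <- function(lo, hi, win) {
  if (is.null(win) || nrow(win) == 0) return(0)
  sum(pmax(0, pmin(hi, win$end_s) - pmax(lo, win$start_s)))
}

#' Set difference a \ b for merged, sorted interval tables.
#' @noRd
interval_difference <- function(a, b) {
  if (is.null(b) || nrow(b) == 0 || is.null(a) || nrow(a) == 0) return(a)
  as <- a$start_s; ae <- a$end_s
  bs <- b$start_s; be <- b$end_s
  cap <- nrow(a) + nrow(b) + 1L
  out_s <- numeric(cap); out_e <- numeric(cap); m <- 0L
  for (k in seq_along(as)) {
    lo <- as[k]; hi <- ae[k]
    idx <- which(be > lo & bs < hi)
    cur <- lo
    for (j in idx) {
      if (bs[j] > cur) {
        m <- m + 1L
        if (m > length(out_s)) { out_s <- c(out_s, numeric(cap)); out_e <- c(out_e, numeric(cap)) }
        out_s[m] <- cur; out_e[m] <- bs[j]
      }
      cur <- max(cur, be[j])
    }
    if (cur < hi) {
      m <- m + 1L
      if (m > length(out_s)) { out_s <- c(out_s, numeric(cap)); out_e <- c(out_e, numeric(cap)) }
      out_s[m] <- cur; out_e[m] <- hi
    }
  }
  data.frame(start_s = out_s[seq_len(m)], end_s = out_e[seq_len(m)])
}

#' Per-hour overlap (s) of a set of intervals with each clock hour.
#' @noRd
hour_overlap <- function(intervals, n_hours) {
  acc <- numeric(n_hours)
  if (is.null(intervals) || nrow(intervals) == 0) return(acc)
  ss <- intervals$start_s; ee <- intervals$end_s
  for (k in seq_along(ss)) {
    lo <- ss[k]; hi <- ee[k]
    h1 <- max(0L, as.integer(lo %/% 3600))
    h2 <- min(n_hours - 1L, as.integer((hi - 1e-9) %/% 3600))
    if (h2 < h1) next
    for (h in h1:h2) {
      acc[h + 1L] <- acc[h + 1L] +
        max(0, min(hi, (h + 1) * 3600) - max(lo, h * 3600))
    }
  }
  acc
}

#' Merge possibly-overlapping windows into disjoint sorted intervals.
#' @noRd
merge_windows <- function(win) {
  if (is.null(win) || nrow(win) == 0) return(win)
  win <- win[order(win$start_s), , drop = FALSE]
  out_s <- win$start_s[1]; out_e <- win$end_s[1]
  for (k in seq_len(nrow(win))[-1]) {
    if (win$start_s[k] <= out_e[length(out_e)]) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], win$end_s[k])
    } else {
      out_s <- c(out_s, win$start_s[k]); out_e <- c(out_e, win$end_s[k])
    }
  }
  data.frame(start_s = out_s, end_s = out_e)
}

#' Summarize sleep per clock hour with stimulus-window exclusion
#'
#' Hourly sleep is computed from unstimulated epochs: time inside
#' `exclusion_windows` (typically `[onset, onset + 900 s]` per stimulus) is
#' removed from both the sleep tally and the available time, and the hourly
#' value is rescaled to min/hr. Bouts spanning hour boundaries are split
#' proportionally. An hour whose available time is fully excluded is reported
#' as `NA`, not 0.
#'
#' @param bouts A `sleep_bouts` data frame for one fly.
#' @param total_s Total trace duration (s).
#' @param exclusion_windows Optional data frame with `start_s`, `end_s`.
#' @param day_window ZT hours delimiting day, default `c(0, 12)`.
#' @return List of class `sleep_summary`: `hourly` (data frame `hour`, `zt`,
#'   `min_per_hr`), `day_min_per_hr`, `night_min_per_hr`, `mean_bout_min`,
#'   `n_bouts`.
#' @export
summarize_sleep <- function(bouts, total_s, exclusion_windows = NULL,
                            day_window = c(0, 12)) {
  excl <- merge_windows(exclusion_windows)
  n_hours <- as.integer(floor(total_s / 3600))
  hours <- seq_len(n_hours) - 1L
  avail <- 3600 - hour_overlap(excl, n_hours)
  sleep_incl <- hour_overlap(interval_difference(bouts, excl), n_hours)
  # minutes asleep in unstimulated epochs, rescaled to min/hr
  min_per_hr <- ifelse(avail > 0, 3600 * (sleep_incl / avail) / 60, NA_real_)
  zt <- hours %% 24
  day <- zt >= day_window[1] & zt < day_window[2]
  res <- list(
    hourly = data.frame(hour = hours, zt = zt, min_per_hr = min_per_hr),
    day_min_per_hr = mean(min_per_hr[day], na.rm = TRUE),
    night_min_per_hr = mean(min_per_hr[!day], na.rm = TRUE),
    mean_bout_min = if (nrow(bouts) == 0) NA_real_ else
      mean((bouts$end_s - bouts$start_s) / 60),
    n_bouts = nrow(bouts)
  )
  class(res) <- "sleep_summary"
  res
}

#' @export
print.sleep_summary <- function(x, ...) {
  cat(sprintf(
    "<sleep_summary> day %.1f min/hr, night %.1f min/hr, %d bouts (mean %.1f min)\n",
    x$day_min_per_hr, x$night_min_per_hr, x$n_bouts, x$mean_bout_min))
  invisible(x)
}
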