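#' Stimulus-locked mean speed curve
#'
#' Averages speed across flies and trials aligned to stimulus onset, from
#' `pre_s` before to `post_s` after (the analysis window is two minutes prior
#' to and the 15 minutes after each stimulus). Trials without full pre/post
#' coverage are dropped; an optional `include` table restricts the average to
#' selected (fly, stimulus) pairs, e.g. light-on trials or awake flies.
#'
#' @param traces List of `activity_trace` objects (or a single trace).
#' @param schedule A `stimulus_schedule` (or data frame with `stim_id`,
#'   `onset_s`).
#' @param pre_s,post_s Window before/after onset (s).
#' @param include Optional data frame with columns `fly_id` and `stim_id`
#'   selecting the trials to average; `NULL` means all.
#' @return Data frame of class `response_curve` with `t_rel` (s, 0 = onset),
#'   `speed` (mm/s, mean over trials) and attribute `n_trials`.
#' @export
stimulus_locked_mean <- function(traces, schedule, pre_s = 120, post_s = 900,
                                 include = NULL) {
  if (inherits(traces, "activity_trace")) traces <- list(traces)
  fr <- traces[[1]]$frame_rate
  npre <- as.integer(round(pre_s * fr))
  npost <- as.integer(round(post_s * fr))
  grid <- seq(-npre, npost) / fr
  acc <- numeric(length(grid))
  n_trials <- 0L
  for (tr in traces) {
    if (abs(tr$frame_rate - fr) > 1e-9) {
      stop_format("all traces must share one frame rate")
    }
    if (is.null(tr$speed)) tr <- compute_speed(tr)
    stim_ids <- schedule$stim_id
    if (!is.null(include)) {
      stim_ids <- intersect(stim_ids,
                            include$stim_id[include$fly_id == tr$fly_id])
    }
    for (sid in stim_ids) {
      onset <- schedule$onset_s[schedule$stim_id == sid]
      oi <- as.integer(round((onset - tr$t0) * fr)) + 1L
      if (oi - npre < 1L || oi + npost > length(tr$speed)) next
      acc <- acc + tr$speed[(oi - npre):(oi + npost)]
      n_trials <- n_trials + 1L
    }
  }
  if (n_trials == 0L) {
    stop_empty_selection("no trials with full coverage after filtering")
  }
  out <- data.frame(t_rel = grid, speed = acc / n_trials)
  attr(out, "n_trials") <- n_trials
  attr(out, "frame_rate") <- fr
  class(out) <- c("response_curve", "data.frame")
  out
}

#' Fit the single-inactivation exponential response curve
#'
#' Least-squares fit of `B + A * (1 - exp(-t/rise_tau)) * exp(-t/decay_tau)`
#' for t >= 0, with the baseline `B` estimated as the pre-window mean and held
#' fixed. Peak responsiveness is the fitted curve's analytic maximum above
#' baseline, attained at `t* = rise_tau * log(1 + decay_tau/rise_tau)`. If the
#' optimiser fails, the result is flagged and the peak falls back to the
#' maximum of the 5-point median-smoothed curve minus baseline.
#'
#' @param curve A `response_curve`.
#' @return List of class `response_fit`: `B`, `A`, `rise_tau`, `decay_tau`,
#'   `t0` (always 0; the curve is onset-aligned), `t_peak`, `peak_mm_s`,
#'   `converged`, `n_trials`.
#' @export
fit_response_peak <- function(curve) {
  stopifnot(inherits(curve, "response_curve"))
  pre <- curve$t_rel < 0
  if (!any(pre) || !any(curve$t_rel >= 0)) {
    stop_format("curve must cover pre and post windows")
  }
  B <- mean(curve$speed[pre])
  post <- curve[curve$t_rel >= 0, , drop = FALSE]
  sm <- stats::runmed(post$speed, k = 5)
  tt <- post$t_rel
  yy <- post$speed
  resid_fn <- function(p) {
    yy - (B + p[1] * (1 - exp(-tt / p[2])) * exp(-tt / p[3]))
  }
  # data-driven start: decay from the tail log-slope, rise from the observed
  # peak time via t* = rise log(1 + decay/rise), amplitude from the peak value
  im <- which.max(sm)
  pk_obs <- max(sm[im] - B, 0.05)
  t_pk <- max(tt[im], 1)
  tail_i <- which(tt > 3 * t_pk & (sm - B) > 0.05 * pk_obs)
  d0 <- 100
  if (length(tail_i) >= 10) {
    lv <- log(sm[tail_i] - B)
    sl <- stats::cov(tt[tail_i], lv) / stats::var(tt[tail_i])
    if (is.finite(sl) && sl < 0) d0 <- min(max(-1 / sl, 5), 2000)
  }
  r0 <- if (t_pk < 0.95 * d0) {
    tryCatch(stats::uniroot(function(r) r * log(1 + d0 / r) - t_pk,
                            c(0.02, 590))$root,
             error = function(e) 5)
  } else 5
  pk0 <- kernel_peak(1, r0, d0)$peak
  A0 <- pk_obs / max(pk0, 0.1)
  starts <- list(c(A = A0, rise = r0, decay = d0),
                 c(A = pk_obs, rise = 5, decay = 100))
  fit <- NULL
  for (st in starts) {
    cand <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         lower = c(0, 1e-2, 1e-1), upper = c(1e4, 600, 5000),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(cand) && cand$info %in% 1:4 &&
        (is.null(fit) || cand$deviance < fit$deviance)) {
      fit <- cand
    }
  }
  if (is.null(fit)) {
    out <- list(B = B, A = NA_real_, rise_tau = NA_real_, decay_tau = NA_real_,
                t0 = 0, t_peak = NA_real_,
                peak_mm_s = max(max(sm) - B, 0), converged = FALSE)
  } else {
    cf <- fit$par
    pk <- kernel_peak(cf[["A"]], cf[["rise"]], cf[["decay"]])
    out <- list(B = B, A = cf[["A"]], rise_tau = cf[["rise"]],
                decay_tau = cf[["decay"]], t0 = 0, t_peak = pk$t_peak,
                peak_mm_s = pk$peak, converged = TRUE)
  }
  out$n_trials <- attr(curve, "n_trials")
  class(out) <- "response_fit"
  out
}

#' @export
print.response_fit <- function(x, ...) {
  cat(sprintf(
    "<response_fit> peak %.3f mm/s at %.1f s (B=%.3f, A=%.3f, rise=%.1f s, decay=%.1f s)%s\n",
    x$peak_mm_s, x$t_peak, x$B, x$A, x$rise_tau, x$decay_tau,
    if (x$converged) "" else " [fallback]"))
  invisible(x)
}

#' Responder call for one stimulus
#'
#' A fly responds if its cumulative path length over the minute following the
#' stimulus reaches `threshold_mm` (3 mm, about three body lengths). A fly is
#' immobile at the stimulus if it made no supra-threshold movement during the
#' preceding minute; `immobility_age_s` is the time since its last movement.
#' Calls whose pre or post window is truncated by the trace edge are excluded
#' (returned as `NULL`), never defaulted.
#'
#' @param trace An `activity_trace`.
#' @param onset_s Stimulus onset (s).
#' @param immobility_eps Movement floor (mm/s).
#' @param threshold_mm Displacement threshold (mm), default 3.
#' @param stim_id Identifier carried into the result.
#' @return One-row data frame (`fly_id`, `stim_id`, `immobile_at_stim`,
#'   `moved_prior_min`, `immobility_age_s`, `displacement_mm`, `responder`),
#'   or `NULL` if the window is truncated.
#' @export
call_responder <- function(trace, onset_s, immobility_eps = 0.5,
                           threshold_mm = 3, stim_id = NA_integer_) {
  stopifnot(inherits(trace, "activity_trace"))
  if (is.null(trace$speed)) trace <- compute_speed(trace)
  fr <- trace$frame_rate
  n60 <- as.integer(round(60 * fr))
  oi <- as.integer(round((onset_s - trace$t0) * fr)) + 1L
  if (oi - n60 < 1L || oi + n60 > length(trace$speed)) return(NULL)
  post <- trace$speed[(oi + 1L):(oi + n60)]
  displacement <- sum(post) / fr  # sum |dx| = sum speed * dt
  pre <- trace$speed[(oi - n60 + 1L):oi]
  moved <- any(pre > immobility_eps)
  age <- immobility_age(trace$speed, oi, fr, immobility_eps)
  data.frame(fly_id = trace$fly_id, stim_id = stim_id,
             immobile_at_stim = !moved, moved_prior_min = moved,
             immobility_age_s = age,
             displacement_mm = displacement,
             responder = displacement >= threshold_mm)
}

#' Responder calls for a whole cohort
#'
#' @param traces List of `activity_trace` objects.
#' @param schedule Stimulus schedule.
#' @inheritParams call_responder
#' @return Data frame of calls (truncated windows dropped), one row per
#'   retained (fly, stimulus) pair, with the schedule's `light_on` flag
#'   joined in.
#' @export
call_responders <- function(traces, schedule, immobility_eps = 0.5,
                            threshold_mm = 3) {
  if (inherits(traces, "activity_trace")) traces <- list(traces)
  rows <- list()
  for (tr in traces) {
    if (is.null(tr$speed)) tr <- compute_speed(tr)
    for (k in seq_len(nrow(schedule))) {
      r <- call_responder(tr, schedule$onset_s[k], immobility_eps,
                          threshold_mm, stim_id = schedule$stim_id[k])
      if (!is.null(r)) {
        r$light_on <- schedule$light_on[k] %||% FALSE
        rows[[length(rows) + 1L]] <- r
      }
    }
  }
  do.call(rbind, rows)
}

#' Sleep intensity: fraction of immobile flies responding
#'
#' Lower values indicate deeper sleep. The input must already be restricted
#' to immobile calls; mixing in awake calls is a contract violation. With no
#' immobile calls the result is `NA` (missing), not 0.
#'
#' @param calls Responder calls with `immobile_at_stim` all `TRUE`.
#' @return Fraction in `[0, 1]` with attribute `n` (immobile call count), or
#'   `NA` when `n = 0`.
#' @export
sleep_intensity <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0) {
    return(structure(NA_real_, n = 0L))
  }
  if (!all(calls$immobile_at_stim)) {
    stop_contract("sleep_intensity requires immobile calls only")
  }
  structure(mean(calls$responder), n = nrow(calls))
}

#' Sleep intensity by prior-immobility bin
#'
#' Immobile calls are assigned to half-open 5-min bins of prior immobility
#' (`[0,5), [5,10), ..., [25,30)` minutes) for the first 30 minutes of
#' inactivity; calls with 30 min or more go to a separate overflow bin.
#'
#' @param calls Responder calls; awake calls are dropped.
#' @return Data frame with `bin_lo_min`, `bin_hi_min`, `n`, `responders`,
#'   `fraction` (NA for empty bins); the final row is the overflow bin.
#' @export
intensity_by_inactivity_bin <- function(calls) {
  calls <- calls[calls$immobile_at_stim, , drop = FALSE]
  lo <- seq(0, 25, by = 5)
  hi <- lo + 5
  age_min <- calls$immobility_age_s / 60
  bin_of <- findInterval(age_min, c(lo, 30))  # 1..6 in-range, 7 overflow
  out <- data.frame(bin_lo_min = c(lo, 30), bin_hi_min = c(hi, Inf))
  out$n <- vapply(seq_len(7), function(b) sum(bin_of == b), integer(1))
  out$responders <- vapply(seq_len(7), function(b) {
    sum(calls$responder[bin_of == b])
  }, integer(1))
  out$fraction <- ifelse(out$n > 0, out$responders / out$n, NA_real_)
  out
}

#' Awake peak responsiveness
#'
#' Restricts the stimulus-locked average to trials in which the fly moved
#' during the minute before the stimulus (awake flies), then fits the
#' response curve. Raises an empty-selection error when no awake trials
#' exist.
#'
#' @inheritParams stimulus_locked_mean
#' @inheritParams call_responder
#' @return A `response_fit`.
#' @export
awake_peak_responsiveness <- function(traces, schedule, pre_s = 120,
                                      post_s = 900, immobility_eps = 0.5) {
  calls <- call_responders(traces, schedule, immobility_eps)
  awake <- calls[calls$moved_prior_min, c("fly_id", "stim_id")]
  if (is.null(awake) || nrow(awake) == 0) {
    stop_empty_selection("no awake trials")
  }
  curve <- stimulus_locked_mean(traces, schedule, pre_s, post_s,
                                include = awake)
  fit_response_peak(curve)
}

#' Per-fly day/night sleep and peak-responsiveness metrics
#'
#' Runs the full behavioral pipeline per fly: speed, sleep bouts, hourly sleep
#' averaged over unstimulated epochs (excluding `[onset, onset + 900 s]`
#' around each stimulus), and a fitted response peak per circadian window from
#' that fly's stimulus-locked mean. This is the per-fly table behind the
#' sleep-versus-responsiveness correlations.
#'
#' @param traces List of `activity_trace` objects.
#' @param schedule Stimulus schedule.
#' @param immobility_eps Movement floor (mm/s).
#' @param day_window ZT day window.
#' @param pre_s,post_s Response-curve window (s).
#' @return Data frame, one row per fly: sleep (min/hr) and fitted peak
#'   (mm/s) per window, mean bout length, fit convergence flags.
#' @export
cohort_arousal_metrics <- function(traces, schedule, immobility_eps = 0.5,
                                   day_window = c(0, 12), pre_s = 120,
                                   post_s = 900) {
  if (inherits(traces, "activity_trace")) traces <- list(traces)
  excl <- data.frame(start_s = schedule$onset_s,
                     end_s = schedule$onset_s + post_s)
  stim_day <- is_day(schedule$onset_s, day_window)
  rows <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    tr <- compute_speed(traces[[i]])
    total_s <- length(tr$x) / tr$frame_rate
    bouts <- detect_sleep_bouts(tr, immobility_eps)
    slp <- summarize_sleep(bouts, total_s, exclusion_windows = excl,
                           day_window = day_window)
    fit_window <- function(day) {
      ids <- schedule$stim_id[stim_day == day]
      if (length(ids) == 0) return(list(peak = NA_real_, ok = NA))
      inc <- data.frame(fly_id = tr$fly_id, stim_id = ids)
      fit <- tryCatch(
        fit_response_peak(
          stimulus_locked_mean(list(tr), schedule, pre_s, post_s,
                               include = inc)),
        error = function(e) NULL)
      if (is.null(fit)) list(peak = NA_real_, ok = FALSE)
      else list(peak = fit$peak_mm_s, ok = fit$converged)
    }
    fd <- fit_window(TRUE)
    fn <- fit_window(FALSE)
    rows[[i]] <- data.frame(
      fly_id = tr$fly_id,
      sleep_day_min_hr = slp$day_min_per_hr,
      sleep_night_min_hr = slp$night_min_per_hr,
      mean_bout_min = slp$mean_bout_min,
      peak_day = fd$peak, peak_day_converged = fd$ok,
      peak_night = fn$peak, peak_night_converged = fn$ok
    )
  }
  do.call(rbind, rows)
}
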