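#' Configuration for a synthetic behavioral cohort
#'
#' Defines a cohort of flies tracked in tubes under a 12:12 light:dark cycle,
#' probed with trains of mechanical vibrations (collapsed to their onset time;
#' the 4.2 s train is short relative to the 60 s response window). Flies follow
#' a two-state (active/quiescent) semi-Markov model with geometric dwell times
#' switching parameters at ZT0/ZT12. Each fly carries a latent sleep propensity
#' per circadian window and a latent response amplitude; the correlation
#' between propensity and amplitude is planted per window
#' (`planted_R_day`/`planted_R_night`).
#'
#' Vibration responses are modelled as a transient speed increment
#' `A * (1 - exp(-t/rise_tau)) * exp(-t/decay_tau)` added to the baseline
#' speed when a fly responds. Response probability depends on the fly's state:
#' awake flies respond with `p_respond_awake`; immobile flies respond with a
#' probability read from `response_prob_by_immobility` according to the
#' duration of immobility preceding the stimulus (5-min bins over 0-30 min,
#' `response_prob_overflow` beyond).
#'
#' @param n_flies Number of flies (> 0).
#' @param days Number of 24 h days recorded.
#' @param frame_rate Tracking frame rate in Hz. `60 * frame_rate` must be an
#'   integer (states switch on minute boundaries).
#' @param day_window ZT hours delimiting the day, default `c(0, 12)`.
#' @param p_fall_asleep_day,p_fall_asleep_night Per-minute probability of an
#'   active fly becoming quiescent. Zero means no quiescence at all.
#' @param sleep_dwell_mean_day,sleep_dwell_mean_night Mean quiescent dwell
#'   time (minutes, geometric).
#' @param sleep_frac_sd Between-fly standard deviation of the stationary
#'   quiescent-time fraction (the sleep-propensity spread the planted
#'   correlations act on).
#' @param response_amplitude_mean,response_amplitude_sd Mean and between-fly SD
#'   of the response-kernel amplitude (mm/s).
#' @param response_kernel Named numeric, `c(rise_tau = , decay_tau = )` in
#'   seconds.
#' @param response_prob_by_immobility Probabilities for immobility bins
#'   `[0,5), [5,10), ..., [25,30)` minutes.
#' @param response_prob_overflow Probability for immobility >= 30 min.
#' @param p_respond_awake Response probability for flies that moved within the
#'   minute before the stimulus.
#' @param planted_R_day,planted_R_night Planted correlation (in `[-1, 1]`)
#'   between per-fly sleep propensity and response amplitude, per window.
#' @param dfb_activation_factor Multiplier (<= 1) applied to the response
#'   amplitude for stimuli delivered during light-on (optogenetic activation).
#' @param light_on_windows Optional data frame (`start_s`, `end_s`) of red
#'   light intervals; stimuli inside them are flagged `light_on`.
#' @param stimulus_protocol `"hourly"` (one train per hour, mid-hour) or
#'   `"acute_15min"` (one train every 15 min, alternating light-on/off trials
#'   with light 60 s before to 180 s after the stimulus).
#' @param tube_length_mm Tube length (positions fold back at the ends).
#' @param active_speed_mean Mean walking speed while active (mm/s).
#' @param active_speed_shape Gamma shape of per-frame active speeds.
#' @param quiescent_jitter_sd SD (mm) of tracking jitter while immobile.
#' @param immobility_eps Speed floor (mm/s) distinguishing movement from
#'   tracking jitter, used for the generator's immobility bookkeeping.
#' @param seed Root integer seed; per-fly substreams are derived from it.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_flies = 225,
                          days = 3,
                          frame_rate = 1,
                          day_window = c(0, 12),
                          p_fall_asleep_day = 0.054,
                          p_fall_asleep_night = 0.093,
                          sleep_dwell_mean_day = 10,
                          sleep_dwell_mean_night = 20,
                          sleep_frac_sd = 0.16,
                          response_amplitude_mean = 2,
                          response_amplitude_sd = 0.6,
                          response_kernel = c(rise_tau = 5, decay_tau = 120),
                          response_prob_by_immobility =
                            c(0.55, 0.40, 0.30, 0.22, 0.17, 0.13),
                          response_prob_overflow = 0.10,
                          p_respond_awake = 0.95,
                          planted_R_day = 0,
                          planted_R_night = -0.372,
                          dfb_activation_factor = 1,
                          light_on_windows = NULL,
                          stimulus_protocol = c("hourly", "acute_15min"),
                          tube_length_mm = 65,
                          active_speed_mean = 2,
                          active_speed_shape = 4,
                          quiescent_jitter_sd = 0.03,
                          immobility_eps = 0.5,
                          seed = 1L) {
  stimulus_protocol <- match.arg(stimulus_protocol)
  cfg <- list(
    n_flies = n_flies, days = days, frame_rate = frame_rate,
    day_window = day_window,
    p_fall_asleep_day = p_fall_asleep_day,
    p_fall_asleep_night = p_fall_asleep_night,
    sleep_dwell_mean_day = sleep_dwell_mean_day,
    sleep_dwell_mean_night = sleep_dwell_mean_night,
    sleep_frac_sd = sleep_frac_sd,
    response_amplitude_mean = response_amplitude_mean,
    response_amplitude_sd = response_amplitude_sd,
    response_kernel = response_kernel,
    response_prob_by_immobility = response_prob_by_immobility,
    response_prob_overflow = response_prob_overflow,
    p_respond_awake = p_respond_awake,
    planted_R_day = planted_R_day, planted_R_night = planted_R_night,
    dfb_activation_factor = dfb_activation_factor,
    light_on_windows = light_on_windows,
    stimulus_protocol = stimulus_protocol,
    tube_length_mm = tube_length_mm,
    active_speed_mean = active_speed_mean,
    active_speed_shape = active_speed_shape,
    quiescent_jitter_sd = quiescent_jitter_sd,
    immobility_eps = immobility_eps,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' @noRd
validate_cohort_config <- function(cfg) {
  if (!is.numeric(cfg$n_flies) || cfg$n_flies < 1) {
    stop_config("n_flies must be a positive count")
  }
  if (cfg$days < 1) stop_config("days must be >= 1")
  if (!is.numeric(cfg$frame_rate) || cfg$frame_rate <= 0) {
    stop_config("frame_rate must be > 0")
  }
  if (abs(60 * cfg$frame_rate - round(60 * cfg$frame_rate)) > 1e-9) {
    stop_config("60 * frame_rate must be an integer")
  }
  check_prob(c(cfg$p_fall_asleep_day, cfg$p_fall_asleep_night),
             "p_fall_asleep")
  check_prob(cfg$response_prob_by_immobility, "response_prob_by_immobility")
  check_prob(c(cfg$response_prob_overflow, cfg$p_respond_awake),
             "response probabilities")
  for (r in c(cfg$planted_R_day, cfg$planted_R_night)) {
    if (!is.finite(r) || abs(r) > 1) stop_config("|planted_R| must be <= 1")
  }
  if (cfg$response_amplitude_mean < 0 || cfg$response_amplitude_sd < 0) {
    stop_config("response amplitudes must be >= 0")
  }
  if (cfg$dfb_activation_factor < 0 || cfg$dfb_activation_factor > 1) {
    stop_config("dfb_activation_factor must lie in [0, 1]")
  }
  if (any(cfg$response_kernel <= 0) ||
      !all(c("rise_tau", "decay_tau") %in% names(cfg$response_kernel))) {
    stop_config("response_kernel needs positive rise_tau and decay_tau")
  }
  invisible(cfg)
}

#' Analytic peak of the response kernel family
#'
#' For `f(t) = A (1 - exp(-t/rise)) exp(-t/decay)` the maximum above baseline
#' is attained at `t* = rise * log(1 + decay/rise)`.
#'
#' @param A Amplitude.
#' @param rise_tau,decay_tau Time constants (s).
#' @return List with `t_peak` (s) and `peak` (same units as `A`).
#' @export
kernel_peak <- function(A, rise_tau, decay_tau) {
  t_star <- rise_tau * log(1 + decay_tau / rise_tau)
  list(t_peak = t_star,
       peak = A * (1 - exp(-t_star / rise_tau)) * exp(-t_star / decay_tau))
}

#' @noRd
response_kernel_values <- function(t, rise_tau, decay_tau) {
  (1 - exp(-t / rise_tau)) * exp(-t / decay_tau)
}

#' Build the stimulus schedule implied by a cohort configuration
#'
#' The mechanical stimulus is a train of five 0.2 s, 2.4 g vibrations 0.8 s
#' apart; the schedule stores the train onset (the train is collapsed to a
#' point event for analysis).
#'
#' @param config A [cohort_config()].
#' @return A `stimulus_schedule` data frame with columns `stim_id`, `onset_s`,
#'   `light_on` and the train specification as attributes.
#' @export
stimulus_schedule <- function(config) {
  total_s <- config$days * 86400
  if (config$stimulus_protocol == "hourly") {
    onsets <- seq(1800, total_s - 1800, by = 3600)
    light <- rep(FALSE, length(onsets))
    if (!is.null(config$light_on_windows)) {
      w <- config$light_on_windows
      light <- vapply(onsets, function(o) {
        any(o >= w$start_s & o < w$end_s)
      }, logical(1))
    }
  } else {
    onsets <- seq(450, total_s - 900, by = 900)
    light <- (seq_along(onsets) %% 2) == 0  # alternating trials
  }
  sched <- data.frame(stim_id = seq_along(onsets),
                      onset_s = onsets,
                      light_on = light)
  attr(sched, "train") <- c(n_pulses = 5, pulse_s = 0.2, gap_s = 0.8,
                            intensity_g = 2.4)
  class(sched) <- c("stimulus_schedule", "data.frame")
  sched
}

#' @noRd
zt_hours <- function(t_s) (t_s / 3600) %% 24

#' @noRd
is_day <- function(t_s, day_window = c(0, 12)) {
  z <- zt_hours(t_s)
  z >= day_window[1] & z < day_window[2]
}

#' Simulate a behavioral cohort with known planted parameters
#'
#' Generates one position trace per fly plus the stimulus schedule and a
#' ground-truth record of every planted quantity the downstream metrics
#' estimate: per-fly sleep-propensity latents and stationary sleep fractions,
#' per-fly response-amplitude targets, and the per-stimulus response
#' probability and responder outcome.
#'
#' Per-fly latents: a shared amplitude factor `v` and window-specific
#' propensity latents `u_w = R_w * v + sqrt(1 - R_w^2) * e_w` plant
#' `cor(u_w, v) = planted_R_w`. The per-stimulus kernel amplitude is the fly's
#' amplitude target divided by its realised responder fraction in that window,
#' so the fly's mean evoked response over all window trials -- the quantity
#' the response-curve fit measures -- equals the planted target.
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort_sim` with elements `traces` (list of
#'   `activity_trace`), `schedule` (a [stimulus_schedule()]) and
#'   `ground_truth` (list with `flies` and `stimuli` data frames).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  sched <- stimulus_schedule(config)
  fr <- config$frame_rate
  n_frames <- as.integer(round(config$days * 86400 * fr))
  kern <- config$response_kernel

  # fly-level latents under the root seed
  set.seed(config$seed)
  n <- as.integer(config$n_flies)
  v <- rnorm(n)
  u_day <- config$planted_R_day * v +
    sqrt(1 - config$planted_R_day^2) * rnorm(n)
  u_night <- config$planted_R_night * v +
    sqrt(1 - config$planted_R_night^2) * rnorm(n)
  amp_target <- pmax(config$response_amplitude_mean +
                       config$response_amplitude_sd * v, 0.1)

  base_frac <- function(p_fall, dwell) {
    if (p_fall <= 0) 0 else (p_fall * dwell) / (1 + p_fall * dwell)
  }
  f_day_base <- base_frac(config$p_fall_asleep_day, config$sleep_dwell_mean_day)
  f_night_base <- base_frac(config$p_fall_asleep_night,
                            config$sleep_dwell_mean_night)
  frac_of <- function(base, u) {
    if (base <= 0) rep(0, length(u)) else pmin(pmax(base + config$sleep_frac_sd * u, 0.02), 0.98)
  }
  f_day <- frac_of(f_day_base, u_day)
  f_night <- frac_of(f_night_base, u_night)

  pk <- kernel_peak(1, kern[["rise_tau"]], kern[["decay_tau"]])

  traces <- vector("list", n)
  stim_rows <- vector("list", n)
  for (i in seq_len(n)) {
    fly <- simulate_fly(i, config, sched, n_frames,
                        f_day[i], f_night[i], amp_target[i])
    traces[[i]] <- fly$trace
    stim_rows[[i]] <- fly$stim
  }

  flies <- data.frame(
    fly_id = seq_len(n),
    u_day = u_day, u_night = u_night, v = v,
    sleep_frac_day = f_day, sleep_frac_night = f_night,
    amp_target = amp_target,
    peak_target = amp_target * pk$peak
  )
  gt <- list(flies = flies,
             stimuli = do.call(rbind, stim_rows),
             kernel_peak_factor = pk$peak,
             kernel_t_peak = pk$t_peak,
             config = config)
  structure(list(traces = traces, schedule = sched, ground_truth = gt),
            class = "cohort_sim")
}

#' Simulate one fly: minute-level state chain, per-frame speeds, stimulus
#' responses with realised-fraction amplitude normalisation, folded position.
#' @noRd
simulate_fly <- function(i, config, sched, n_frames, frac_day, frac_night,
                         amp_target) {
  set.seed(child_seed(config$seed, i))
  fr <- config$frame_rate
  fpm <- as.integer(round(60 * fr))
  n_min <- as.integer(config$days * 1440)

  # per-window per-minute transition probabilities from the fly's stationary
  # fraction, holding the dwell mean fixed
  p_wake <- c(day = 1 / config$sleep_dwell_mean_day,
              night = 1 / config$sleep_dwell_mean_night)
  p_fall <- c(
    day = if (frac_day <= 0) 0 else
      min(frac_day / (config$sleep_dwell_mean_day * (1 - frac_day)), 0.999),
    night = if (frac_night <= 0) 0 else
      min(frac_night / (config$sleep_dwell_mean_night * (1 - frac_night)), 0.999)
  )

  state_min <- simulate_state_chain(n_min, config$day_window, p_fall, p_wake,
                                    c(day = frac_day, night = frac_night))

  quiescent <- rep(state_min, each = fpm)  # TRUE = quiescent
  n_active <- sum(!quiescent)
  speed <- numeric(n_frames)
  if (n_active > 0) {
    shp <- config$active_speed_shape
    speed[!quiescent] <- rgamma(n_active, shape = shp,
                                scale = config$active_speed_mean / shp)
  }
  nq <- sum(quiescent)
  if (nq > 0 && config$quiescent_jitter_sd > 0) {
    speed[quiescent] <- abs(rnorm(nq, sd = config$quiescent_jitter_sd)) * fr
  }

  # chronological responder pass with provisional (unit-scale) kernels
  onsets <- sched$onset_s
  day_stim <- is_day(onsets, config$day_window)
  n_stim <- length(onsets)
  kern <- config$response_kernel
  k_len <- as.integer(round(900 * fr))
  k_t <- (seq_len(k_len)) / fr
  k_shape <- response_kernel_values(k_t, kern[["rise_tau"]], kern[["decay_tau"]])
  eps <- config$immobility_eps

  responder <- logical(n_stim)
  age_s <- numeric(n_stim)
  p_used <- numeric(n_stim)
  work <- speed
  for (s in seq_len(n_stim)) {
    oi <- as.integer(round(onsets[s] * fr)) + 1L  # frame index at onset
    if (oi > n_frames) break
    age_s[s] <- immobility_age(work, oi, fr, eps)
    p_used[s] <- response_probability(age_s[s], config)
    responder[s] <- runif(1) < p_used[s]
    if (responder[s]) {
      idx <- oi + seq_len(min(k_len, n_frames - oi))
      work[idx] <- work[idx] + amp_target * k_shape[seq_along(idx)]
    } else if (age_s[s] >= 60) {
      # a sleeping fly that does not respond stays quiescent through the
      # scored minute: the responder call is exactly the planted outcome
      n60 <- as.integer(round(60 * fr))
      idx <- oi + seq_len(min(n60, n_frames - oi))
      j <- if (config$quiescent_jitter_sd > 0) {
        abs(rnorm(length(idx), sd = config$quiescent_jitter_sd)) * fr
      } else 0
      speed[idx] <- j
      work[idx] <- j
    }
  }

  # realised responder fraction per window -> amplitude normalisation
  frac_resp <- function(sel) {
    if (!any(sel)) return(1)
    max(mean(responder[sel]), 1 / sum(sel))
  }
  scale_w <- c(day = 1 / frac_resp(day_stim), night = 1 / frac_resp(!day_stim))

  amp_applied <- numeric(n_stim)
  for (s in which(responder)) {
    oi <- as.integer(round(onsets[s] * fr)) + 1L
    a <- amp_target * scale_w[[if (day_stim[s]) "day" else "night"]]
    if (sched$light_on[s]) a <- a * config$dfb_activation_factor
    amp_applied[s] <- a
    idx <- oi + seq_len(min(k_len, n_frames - oi))
    speed[idx] <- speed[idx] + a * k_shape[seq_along(idx)]
  }

  # position: direction random walk folded into the tube
  dir <- 1 - 2 * (runif(n_frames) < 0.5)
  x <- fold_position(config$tube_length_mm / 2 + cumsum(speed * dir / fr),
                     config$tube_length_mm)

  # positions are folded into [0, L] by construction; skip revalidation
  trace <- structure(list(fly_id = i, x = x, frame_rate = fr, t0 = 0,
                          tube_length = config$tube_length_mm),
                     class = "activity_trace")
  stim <- data.frame(fly_id = i, stim_id = sched$stim_id,
                     onset_s = onsets,
                     window = ifelse(day_stim, "day", "night"),
                     light_on = sched$light_on,
                     age_s = age_s, p_respond = p_used,
                     responder = responder, amp_applied = amp_applied)
  list(trace = trace, stim = stim)
}

#' Minute-level two-state chain via geometric dwell sampling within 12 h
#' blocks (dwells are memoryless, so restarting at block boundaries with the
#' new parameters is exact). Returns logical vector, TRUE = quiescent.
#' @noRd
simulate_state_chain <- function(n_min, day_window, p_fall, p_wake, frac) {
  out <- logical(n_min)
  # window label per minute
  day_min <- is_day((seq_len(n_min) - 1) * 60 + 30, day_window)
  first_w <- if (day_min[1]) "day" else "night"
  asleep <- runif(1) < frac[[first_w]]
  pos <- 1L
  blocks <- rle(day_min)
  b_end <- cumsum(blocks$lengths)
  b_start <- c(1L, head(b_end, -1) + 1L)
  for (b in seq_along(blocks$lengths)) {
    w <- if (blocks$values[b]) "day" else "night"
    pos <- b_start[b]
    while (pos <= b_end[b]) {
      p_exit <- if (asleep) p_wake[[w]] else p_fall[[w]]
      # p_exit = 0 means the state is absorbing within this block
      dwell <- if (p_exit <= 0) Inf else 1L + rgeom(1, p_exit)
      stay <- min(dwell, b_end[b] - pos + 1L)
      if (asleep) out[pos:(pos + stay - 1L)] <- TRUE
      pos <- pos + stay
      if (dwell <= stay) asleep <- !asleep
    }
  }
  out
}

#' Time (s) since the last supra-threshold frame before `onset_idx`.
#' Lookback capped at 40 min (immobility binning tops out at 30 min, so
#' longer ages are equivalent); flies immobile longer report the cap.
#' @noRd
immobility_age <- function(speed, onset_idx, fr, eps) {
  lb <- max(1L, onset_idx - as.integer(2400 * fr))
  win <- speed[lb:(onset_idx - 1L)]
  act <- which(win > eps)
  if (length(act) == 0) (onset_idx - lb) / fr
  else (length(win) - act[length(act)]) / fr
}

#' @noRd
response_probability <- function(age_s, config) {
  if (age_s < 60) return(config$p_respond_awake)
  bin <- floor(age_s / 300) + 1  # 5-min bins
  probs <- config$response_prob_by_immobility
  if (bin > length(probs)) config$response_prob_overflow else probs[[bin]]
}
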