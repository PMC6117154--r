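# Independent oracles and fixture builders used across the suite. These are
# deliberately naive (frame loops, direct sums) so they share no code path
# with the package implementations they check.

# Brute-force sleep-bout scan: walk the frames, track runs of immobility,
# emit maximal runs of at least min_bout_s.
oracle_bouts <- function(speed, fr, eps = 0.5, min_bout_s = 300, t0 = 0) {
  starts <- numeric(0); ends <- numeric(0)
  run_start <- NA
  for (i in seq_along(speed)) {
    if (speed[i] <= eps) {
      if (is.na(run_start)) run_start <- i
    } else {
      if (!is.na(run_start) && (i - run_start) / fr >= min_bout_s) {
        starts <- c(starts, run_start); ends <- c(ends, i - 1)
      }
      run_start <- NA
    }
  }
  if (!is.na(run_start) &&
      (length(speed) + 1 - run_start) / fr >= min_bout_s) {
    starts <- c(starts, run_start); ends <- c(ends, length(speed))
  }
  data.frame(start_s = t0 + (starts - 1) / fr, end_s = t0 + ends / fr)
}

# Second-resolution interval oracle for hourly sleep with exclusions:
# label every second asleep/excluded and tally per hour.
oracle_hourly_sleep <- function(bouts, excl, n_hours) {
  secs <- seq_len(n_hours * 3600) - 1  # second index = [t, t+1)
  asleep <- rep(FALSE, length(secs))
  for (k in seq_len(nrow(bouts))) {
    idx <- secs >= bouts$start_s[k] & secs < bouts$end_s[k]
    asleep[idx] <- TRUE
  }
  excluded <- rep(FALSE, length(secs))
  if (!is.null(excl)) {
    for (k in seq_len(nrow(excl))) {
      excluded[excluded | (secs >= excl$start_s[k] & secs < excl$end_s[k])] <- TRUE
    }
  }
  vapply(seq_len(n_hours) - 1, function(h) {
    in_h <- secs >= h * 3600 & secs < (h + 1) * 3600
    avail <- sum(in_h & !excluded)
    if (avail == 0) return(NA_real_)
    60 * sum(in_h & asleep & !excluded) / avail
  }, numeric(1))
}

# Direct complex Morlet coefficient at one (frequency, sample) point.
oracle_morlet_coef <- function(x, fs, f, t_idx, width = 30, cutoff = 3) {
  sd_t <- width / (2 * pi * f)
  K <- floor(cutoff * sd_t * fs)
  tt <- (-K:K) / fs
  w <- exp(-tt^2 / (2 * sd_t^2)) * exp(2i * pi * f * tt)
  w <- w / sqrt(sum(Mod(w)^2))
  idx <- t_idx + (-K:K)
  stopifnot(all(idx >= 1), all(idx <= length(x)))
  sum(x[idx] * Conj(w))
}

# Build an activity trace directly from a target speed profile (1 Hz):
# straight-line walk, no folding (tube long enough for the test).
trace_from_speed <- function(speed, fr = 1, fly_id = 1L, tube_length = 1e6) {
  x <- cumsum(c(0, speed[-1] / fr))
  activity_trace(x, frame_rate = fr, fly_id = fly_id,
                 tube_length = tube_length)
}

# Noise-free response curve from the fitted family.
curve_from_kernel <- function(B, A, rise, decay, pre_s = 120, post_s = 900,
                              fr = 1, noise_sd = 0, n_flies = 1) {
  t_rel <- seq(-pre_s * fr, post_s * fr) / fr
  y <- B + ifelse(t_rel >= 0,
                  A * (1 - exp(-t_rel / rise)) * exp(-t_rel / decay), 0)
  if (noise_sd > 0) {
    noise <- rowMeans(matrix(rnorm(length(y) * n_flies, sd = noise_sd),
                             ncol = n_flies))
    y <- y + noise
  }
  out <- data.frame(t_rel = t_rel, speed = y)
  attr(out, "n_trials") <- n_flies
  attr(out, "frame_rate") <- fr
  class(out) <- c("response_curve", "data.frame")
  out
}
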