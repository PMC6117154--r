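#' Configuration for a synthetic local-field-potential recording
#'
#' Emulates an extracellular recording near the dorsal fan-shaped body:
#' baseline 1/f-shaped broadband noise, a light epoch during which the
#' 1-15 Hz component of the signal is scaled by `stim_band_power_gain`
#' (amplitude gain; power scales with its square), and, for pulsed light, a
#' deterministic deflection of `erp_amplitude` peaking `erp_latency` ms after
#' each pulse onset.
#'
#' @param fs Sampling rate (Hz).
#' @param duration Recording length (s).
#' @param noise_exponent Spectral exponent alpha of the 1/f^alpha baseline
#'   noise.
#' @param noise_amplitude Baseline RMS amplitude (recording units); 0 gives a
#'   noiseless trace.
#' @param stim_band_power_gain Amplitude gain applied to the 1-15 Hz
#'   component during light-on (>= 0; 1 means no effect).
#' @param light_mode `"constant"`, `"pulsed_1hz_5ms"` or `"none"`.
#' @param light_onset,light_duration Light epoch (s).
#' @param erp_amplitude Pulse-locked deflection amplitude (units, >= 0).
#' @param erp_latency Deflection peak latency after pulse onset (ms, in
#'   `[0, 1000)`).
#' @param erp_width Deflection FWHM (ms).
#' @param n_pulses Number of 1 Hz pulses (>= 1), default 120.
#' @param band_drift_sd SD of the slow log-normal drift of the 1-15 Hz
#'   component's amplitude (correlation time ~20 s). Field-potential band
#'   power is nonstationary on the minute scale in vivo; without this the
#'   across-fly spread of baseline-normalised ratios collapses to zero and
#'   null comparisons become degenerate. 0 disables the drift.
#' @param seed Integer seed.
#' @return An `lfp_sim_config` list.
#' @export
lfp_sim_config <- function(fs = 1000, duration = 300,
                           noise_exponent = 1, noise_amplitude = 10,
                           stim_band_power_gain = 1,
                           light_mode = c("constant", "pulsed_1hz_5ms", "none"),
                           light_onset = 60, light_duration = 120,
                           erp_amplitude = 0, erp_latency = 20,
                           erp_width = 5, n_pulses = 120,
                           band_drift_sd = 0.3,
                           seed = 1L) {
  light_mode <- match.arg(light_mode)
  if (fs <= 0) stop_config("fs must be > 0")
  if (stim_band_power_gain < 0) stop_config("gain must be >= 0")
  if (n_pulses < 1) stop_config("n_pulses must be >= 1")
  if (erp_latency < 0 || erp_latency >= 1000) {
    stop_config("erp_latency must lie in [0, 1000) ms")
  }
  if (light_mode != "none" && duration < light_onset + light_duration) {
    stop_config("duration must cover light_onset + light_duration")
  }
  if (light_mode == "pulsed_1hz_5ms" && n_pulses > light_duration) {
    stop_config("n_pulses at 1 Hz cannot exceed light_duration seconds")
  }
  structure(list(fs = fs, duration = duration,
                 noise_exponent = noise_exponent,
                 noise_amplitude = noise_amplitude,
                 stim_band_power_gain = stim_band_power_gain,
                 light_mode = light_mode, light_onset = light_onset,
                 light_duration = light_duration,
                 erp_amplitude = erp_amplitude, erp_latency = erp_latency,
                 erp_width = erp_width, n_pulses = as.integer(n_pulses),
                 band_drift_sd = band_drift_sd,
                 seed = as.integer(seed)),
            class = "lfp_sim_config")
}

#' 1/f^alpha Gaussian noise via spectral shaping, rescaled to a target RMS.
#' @noRd
one_over_f_noise <- function(n, fs, exponent, rms) {
  if (rms <= 0) return(numeric(n))
  white <- rnorm(n)
  X <- fft(white)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  shape <- c(0, f[-1]^(-exponent / 2))
  x <- Re(fft(X * shape, inverse = TRUE)) / n
  x * rms / sd(x)
}

#' Split a signal into its 1-15 Hz component and the remainder (FFT mask).
#' @noRd
band_split <- function(x, fs, band = c(1, 15)) {
  n <- length(x)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  mask <- as.numeric(f >= band[1] & f <= band[2])
  xb <- Re(fft(fft(x) * mask, inverse = TRUE)) / n
  list(band = xb, rest = x - xb)
}

#' Simulate a local-field-potential trace
#'
#' @param config An [lfp_sim_config()].
#' @return An `lfp_trace`: list with `fs`, `signal`, `light` annotations and
#'   `ground_truth` (planted gain, ERP parameters).
#' @export
simulate_lfp_trace <- function(config) {
  stopifnot(inherits(config, "lfp_sim_config"))
  set.seed(config$seed)
  fs <- config$fs
  n <- as.integer(round(config$duration * fs))
  x <- one_over_f_noise(n, fs, config$noise_exponent, config$noise_amplitude)

  pulse_onsets <- numeric(0)
  light_on <- config$light_mode != "none"
  needs_band <- config$noise_amplitude > 0 &&
    (config$band_drift_sd > 0 ||
       (light_on && config$stim_band_power_gain != 1))
  if (needs_band) {
    sp <- band_split(x, fs)
    env <- rep(1, n)
    if (light_on && config$stim_band_power_gain != 1) {
      on_i <- as.integer(round(config$light_onset * fs)) + 1L
      off_i <- as.integer(round((config$light_onset + config$light_duration) * fs))
      ramp_n <- as.integer(round(0.5 * fs))
      env[on_i:off_i] <- config$stim_band_power_gain
      if (ramp_n > 1) {
        g <- config$stim_band_power_gain
        up <- 1 + (g - 1) * (1 - cos(seq(0, pi, length.out = ramp_n))) / 2
        env[on_i:(on_i + ramp_n - 1L)] <- up
        env[(off_i - ramp_n + 1L):off_i] <- rev(up)
      }
    }
    if (config$band_drift_sd > 0) {
      # slow log-normal amplitude drift (AR(1), ~20 s correlation time)
      a <- exp(-1 / (20 * fs))
      drift <- as.numeric(stats::filter(rnorm(n, sd = sqrt(1 - a^2)),
                                        a, method = "recursive"))
      env <- env * exp(config$band_drift_sd * drift)
    }
    x <- sp$rest + env * sp$band
  }

  if (config$light_mode == "pulsed_1hz_5ms") {
    pulse_onsets <- config$light_onset + seq_len(config$n_pulses) - 1
    if (config$erp_amplitude > 0) {
      sigma_s <- config$erp_width / 1000 / (2 * sqrt(2 * log(2)))
      K <- as.integer(ceiling(4 * sigma_s * fs))
      t_k <- (-K:K) / fs  # centred grid: the peak sample is exact
      shape <- -config$erp_amplitude * exp(-t_k^2 / (2 * sigma_s^2))
      for (p in pulse_onsets) {
        peak_i <- as.integer(round((p + config$erp_latency / 1000) * fs)) + 1L
        x <- add_at(x, peak_i - K, shape)
      }
    }
  }

  structure(list(
    fs = fs, signal = x,
    light = list(mode = config$light_mode, onset_s = config$light_onset,
                 duration_s = config$light_duration,
                 pulse_onsets = pulse_onsets),
    ground_truth = list(stim_band_power_gain = config$stim_band_power_gain,
                        erp_amplitude = config$erp_amplitude,
                        erp_latency_ms = config$erp_latency)
  ), class = "lfp_trace")
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace> %.1f s @ %g Hz, light: %s\n",
              length(x$signal) / x$fs, x$fs, x$light$mode))
  invisible(x)
}

#' Construct an LFP trace from a signal vector
#'
#' @param signal Recording-unit samples.
#' @param fs Sampling rate (Hz).
#' @param light Optional light annotation list (`mode`, `onset_s`,
#'   `duration_s`, `pulse_onsets`).
#' @return An `lfp_trace`.
#' @export
lfp_trace <- function(signal, fs, light = list(mode = "none")) {
  if (fs <= 0) stop_format("fs must be > 0")
  structure(list(fs = fs, signal = as.numeric(signal), light = light),
            class = "lfp_trace")
}
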