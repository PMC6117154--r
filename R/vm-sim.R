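#' Configuration for a synthetic membrane-potential recording
#'
#' Emulates an in vivo whole-cell current-clamp recording from a fly central
#' neuron: a stabilised resting potential between -50 and -30 mV, Gaussian
#' recording noise, optional spontaneous single spikes and burst volleys, and
#' an optogenetic light epoch (1 min baseline, 2 min light by default) that
#' depolarises the cell. Burst volleys ride on a plateau depolarisation so the
#' inter-spike potential does not return to rest, the defining feature of
#' burst firing here. Intra-burst peaks are `burst_isi` ms apart.
#'
#' @param fs Sampling rate (Hz), default 10000.
#' @param duration Recording length (s); must cover
#'   `light_onset + light_duration` plus a >= 60 s post window for light
#'   modes other than `"none"`.
#' @param resting_vm Resting potential (mV), default -40.
#' @param noise_sd Recording noise SD (mV).
#' @param cell_class One of `"non_spiking"`, `"single"`, `"burst"`,
#'   `"single_and_burst"`.
#' @param light_mode `"constant"`, `"pulsed_1hz_5ms"` or `"none"`.
#' @param light_onset Light onset (s), default 60 (1 min baseline).
#' @param light_duration Light epoch length (s), default 120.
#' @param evoked_depolarization Light-evoked depolarisation (mV). For pulsed
#'   light this is the mean depolarisation of the composite pulse response
#'   over its first 100 ms.
#' @param evoked_rise_tau,evoked_decay_tau Depolarisation onset/offset time
#'   constants (s) for constant light.
#' @param burst_isi Intra-burst inter-spike interval (ms), default 18.75.
#' @param burst_size Spikes per volley.
#' @param spont_single_rate,spont_burst_rate Spontaneous event rates (Hz).
#' @param evoked_spike Logical: do light pulses evoke an action potential
#'   (spiking cells under pulsed light)?
#' @param secondary_spike_prob Probability that an evoked spike is followed by
#'   a secondary spike 100-500 ms later.
#' @param spike_height Spike amplitude above local potential (mV).
#' @param seed Integer seed.
#' @return A `vm_sim_config` list.
#' @export
vm_sim_config <- function(fs = 10000, duration = 300, resting_vm = -40,
                          noise_sd = 1,
                          cell_class = c("single_and_burst", "non_spiking",
                                         "single", "burst"),
                          light_mode = c("constant", "pulsed_1hz_5ms", "none"),
                          light_onset = 60, light_duration = 120,
                          evoked_depolarization = 8,
                          evoked_rise_tau = 1, evoked_decay_tau = 10,
                          burst_isi = 18.75, burst_size = 3,
                          spont_single_rate = 0.5, spont_burst_rate = 0.1,
                          evoked_spike = TRUE,
                          secondary_spike_prob = 0.4,
                          spike_height = 40,
                          seed = 1L) {
  cell_class <- match.arg(cell_class)
  light_mode <- match.arg(light_mode)
  if (fs <= 0) stop_config("fs must be > 0")
  if (evoked_depolarization < 0) {
    stop_config("evoked_depolarization must be >= 0")
  }
  check_prob(secondary_spike_prob, "secondary_spike_prob")
  if (light_mode != "none" && duration < light_onset + light_duration) {
    stop_config("duration must cover light_onset + light_duration")
  }
  structure(list(fs = fs, duration = duration, resting_vm = resting_vm,
                 noise_sd = noise_sd, cell_class = cell_class,
                 light_mode = light_mode, light_onset = light_onset,
                 light_duration = light_duration,
                 evoked_depolarization = evoked_depolarization,
                 evoked_rise_tau = evoked_rise_tau,
                 evoked_decay_tau = evoked_decay_tau,
                 burst_isi = burst_isi, burst_size = burst_size,
                 spont_single_rate = spont_single_rate,
                 spont_burst_rate = spont_burst_rate,
                 evoked_spike = evoked_spike,
                 secondary_spike_prob = secondary_spike_prob,
                 spike_height = spike_height,
                 seed = as.integer(seed)),
            class = "vm_sim_config")
}

#' Stereotyped spike waveform: fast rise, fast fall, small
#' after-hyperpolarisation. Peak value equals `height`.
#' @noRd
spike_template <- function(fs, height = 40) {
  rise <- seq(0, height, length.out = max(2, round(0.0006 * fs)))
  fall <- seq(height, -3, length.out = max(2, round(0.0010 * fs)))[-1]
  ahp <- seq(-3, 0, length.out = max(2, round(0.0020 * fs)))[-1]
  c(rise, fall, ahp)
}

#' @noRd
add_at <- function(x, start_idx, values) {
  idx <- start_idx + seq_along(values) - 1L
  keep <- idx >= 1L & idx <= length(x)
  x[idx[keep]] <- x[idx[keep]] + values[keep]
  x
}

#' Pulse-response bump, unit-normalised so its mean over the first 100 ms is
#' exactly 1; the planted pulsed depolarisation is then recovered directly by
#' the composite first-100-ms mean.
#' @noRd
pulse_bump <- function(fs, rise_s = 0.005, decay_s = 0.030, support_s = 0.5) {
  t <- seq_len(round(support_s * fs)) / fs
  b <- (1 - exp(-t / rise_s)) * exp(-t / decay_s)
  b / mean(b[t <= 0.1])
}

#' Simulate a membrane-potential trace
#'
#' @param config A [vm_sim_config()].
#' @return A `vm_trace`: list with `fs`, `vm` (mV), `light` annotations
#'   (mode, onset, duration, pulse onsets) and `ground_truth` (planted spike
#'   and volley times, per-pulse secondary-spike outcomes).
#' @export
simulate_vm_trace <- function(config) {
  stopifnot(inherits(config, "vm_sim_config"))
  set.seed(config$seed)
  fs <- config$fs
  n <- as.integer(round(config$duration * fs))
  vm <- rep(config$resting_vm, n)
  if (config$noise_sd > 0) vm <- vm + rnorm(n, sd = config$noise_sd)

  on_i <- as.integer(round(config$light_onset * fs)) + 1L
  off_i <- as.integer(round((config$light_onset + config$light_duration) * fs))
  pulse_onsets <- numeric(0)

  if (config$light_mode == "constant" && config$evoked_depolarization > 0) {
    t_on <- (seq_len(off_i - on_i + 1L) - 1L) / fs
    vm[on_i:off_i] <- vm[on_i:off_i] +
      config$evoked_depolarization * (1 - exp(-t_on / config$evoked_rise_tau))
    level_off <- config$evoked_depolarization *
      (1 - exp(-config$light_duration / config$evoked_rise_tau))
    if (off_i < n) {
      t_off <- (seq_len(n - off_i)) / fs
      vm[(off_i + 1L):n] <- vm[(off_i + 1L):n] +
        level_off * exp(-t_off / config$evoked_decay_tau)
    }
  }

  gt_secondary <- NULL
  spike_times <- list(single = numeric(0), burst = numeric(0),
                      evoked = numeric(0), secondary = numeric(0))
  volleys <- list()
  tmpl <- spike_template(fs, config$spike_height)
  spiking <- config$cell_class != "non_spiking"

  if (config$light_mode == "pulsed_1hz_5ms") {
    n_pulses <- as.integer(floor(config$light_duration))
    pulse_onsets <- config$light_onset + seq_len(n_pulses) - 1
    if (config$evoked_depolarization > 0) {
      bump <- config$evoked_depolarization * pulse_bump(fs)
      for (p in pulse_onsets) {
        vm <- add_at(vm, as.integer(round(p * fs)) + 1L, bump)
      }
    }
    if (spiking && config$evoked_spike) {
      sec <- rbinom(n_pulses, 1, config$secondary_spike_prob) == 1
      sec_lat <- runif(n_pulses, 0.2, 0.4)  # inside the 100-500 ms window
      gt_secondary <- data.frame(pulse_onset = pulse_onsets, secondary = sec,
                                 secondary_latency_s = ifelse(sec, sec_lat, NA))
      for (k in seq_len(n_pulses)) {
        t_spk <- pulse_onsets[k] + 0.005
        vm <- add_at(vm, as.integer(round(t_spk * fs)) + 1L, tmpl)
        spike_times$evoked <- c(spike_times$evoked, t_spk)
        if (sec[k]) {
          t2 <- t_spk + sec_lat[k]
          vm <- add_at(vm, as.integer(round(t2 * fs)) + 1L, tmpl)
          spike_times$secondary <- c(spike_times$secondary, t2)
        }
      }
    }
  }

  if (spiking && config$cell_class %in% c("single", "single_and_burst") &&
      config$spont_single_rate > 0) {
    n_ev <- stats::rpois(1, config$spont_single_rate * config$duration)
    tt <- sort(runif(n_ev, 0.05, config$duration - 0.05))
    tt <- tt[c(TRUE, diff(tt) > 0.05)]
    for (ts in tt) vm <- add_at(vm, as.integer(round(ts * fs)) + 1L, tmpl)
    spike_times$single <- tt
  }

  if (spiking && config$cell_class %in% c("burst", "single_and_burst") &&
      config$spont_burst_rate > 0) {
    n_vol <- stats::rpois(1, config$spont_burst_rate * config$duration)
    starts <- sort(runif(n_vol, 0.5, config$duration - 0.5))
    starts <- starts[c(TRUE, diff(starts) > 0.5)]
    isi_s <- config$burst_isi / 1000
    for (v in seq_along(starts)) {
      pk <- starts[v] + (seq_len(config$burst_size) - 1) * isi_s
      # plateau keeping the inter-spike potential ~10 mV above rest
      plat_len <- as.integer(round((config$burst_size * isi_s + 0.02) * fs))
      ramp <- round(0.005 * fs)
      plat <- 10 * c(seq(0, 1, length.out = ramp),
                     rep(1, max(0, plat_len - 2 * ramp)),
                     seq(1, 0, length.out = ramp))
      vm <- add_at(vm, as.integer(round((starts[v] - 0.005) * fs)) + 1L, plat)
      for (ts in pk) vm <- add_at(vm, as.integer(round(ts * fs)) + 1L, tmpl)
      spike_times$burst <- c(spike_times$burst, pk)
      volleys[[v]] <- pk
    }
  }

  structure(list(
    fs = fs, vm = vm,
    light = list(mode = config$light_mode, onset_s = config$light_onset,
                 duration_s = config$light_duration,
                 pulse_onsets = pulse_onsets),
    ground_truth = list(cell_class = config$cell_class,
                        resting_vm = config$resting_vm,
                        evoked_depolarization = config$evoked_depolarization,
                        spike_times = spike_times, volleys = volleys,
                        secondary = gt_secondary)
  ), class = "vm_trace")
}

#' @export
print.vm_trace <- function(x, ...) {
  cat(sprintf("<vm_trace> %.1f s @ %g Hz, light: %s\n",
              length(x$vm) / x$fs, x$fs, x$light$mode))
  invisible(x)
}
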