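#' Detect action potentials in a membrane-potential trace
#'
#' A spike is a local maximum reached after the voltage slope exceeds
#' `threshold_dvdt`, with prominence (peak minus the minimum over the
#' preceding 5 ms) of at least `min_prominence`. Peaks closer than 2 ms to an
#' accepted peak are suppressed (refractory). Detection is deterministic.
#'
#' @param trace A `vm_trace`.
#' @param threshold_dvdt Slope threshold (mV/ms), default 10.
#' @param min_prominence Minimum prominence (mV), default 5.
#' @return Data frame of class `spike_events`: `peak_time` (s), `peak_vm`
#'   (mV), `trough_after` (mV, minimum over the 5 ms after the peak).
#' @export
detect_spikes <- function(trace, threshold_dvdt = 10, min_prominence = 5) {
  stopifnot(inherits(trace, "vm_trace"))
  fs <- trace$fs
  if (fs < 1000) stop_config("fs below 1 kHz cannot resolve spikes")
  vm <- trace$vm
  # slope over a 0.5 ms span of the 0.5 ms moving-averaged trace: fast spike
  # upstrokes pass, sample-to-sample recording noise does not
  k <- max(1L, as.integer(round(0.0005 * fs)))
  vs <- as.numeric(stats::filter(vm, rep(1 / k, k), sides = 2))
  n <- length(vm)
  slope <- (vs[(1L + k):n] - vs[1:(n - k)]) * fs / k / 1000  # mV/ms
  slope[is.na(slope)] <- 0
  up <- which(slope[-1] >= threshold_dvdt &
                slope[-length(slope)] < threshold_dvdt) + 1L
  w3 <- as.integer(round(0.003 * fs))
  w2 <- as.integer(round(0.002 * fs))
  w5 <- as.integer(round(0.005 * fs))
  refr <- 0.002
  peaks <- numeric(0); pvm <- numeric(0); trough <- numeric(0)
  last_t <- -Inf
  for (i in up) {
    hi <- min(n, i + w3)
    pk <- i + which.max(vm[i:hi]) - 1L
    prom <- vm[pk] - min(vm[max(1L, pk - w2):pk])
    if (prom < min_prominence) next
    t_pk <- (pk - 1L) / fs
    if (t_pk - last_t < refr) next
    last_t <- t_pk
    peaks <- c(peaks, t_pk)
    pvm <- c(pvm, vm[pk])
    trough <- c(trough, min(vm[pk:min(n, pk + w5)]))
  }
  out <- data.frame(peak_time = peaks, peak_vm = pvm, trough_after = trough)
  class(out) <- c("spike_events", "data.frame")
  out
}

#' Estimate the resting membrane potential
#'
#' Median of the pre-light baseline (or the whole trace if no light epoch)
#' after excising 5 ms either side of each detected spike peak; robust to
#' spontaneous spiking.
#'
#' @param trace A `vm_trace`.
#' @param spikes Optional pre-computed `spike_events`.
#' @return Resting potential (mV).
#' @export
estimate_resting_vm <- function(trace, spikes = NULL) {
  fs <- trace$fs
  if (is.null(spikes)) spikes <- detect_spikes(trace)
  end_i <- if (!is.null(trace$light) && trace$light$mode != "none") {
    max(2L, as.integer(round(trace$light$onset_s * fs)))
  } else length(trace$vm)
  keep <- rep(TRUE, end_i)
  w <- as.integer(round(0.005 * fs))
  for (tp in spikes$peak_time) {
    i <- as.integer(round(tp * fs)) + 1L
    if (i - w > end_i) next
    keep[max(1L, i - w):min(end_i, i + w)] <- FALSE
  }
  median(trace$vm[seq_len(end_i)][keep])
}

#' Group spikes into bursts
#'
#' Consecutive spikes belong to one burst when the membrane potential between
#' their peaks fails to return to rest, i.e. its minimum stays more than
#' `burst_margin` mV above the resting potential.
#'
#' @param trace A `vm_trace`.
#' @param spikes `spike_events`.
#' @param resting Resting potential (mV).
#' @param burst_margin Tolerance above rest (mV), default 2.
#' @return Integer vector of group labels, one per spike.
#' @export
group_bursts <- function(trace, spikes, resting, burst_margin = 2) {
  n <- nrow(spikes)
  if (n == 0) return(integer(0))
  grp <- integer(n)
  grp[1] <- 1L
  fs <- trace$fs
  for (k in seq_len(n - 1)) {
    i1 <- as.integer(round(spikes$peak_time[k] * fs)) + 1L
    i2 <- as.integer(round(spikes$peak_time[k + 1] * fs)) + 1L
    inter_min <- min(trace$vm[i1:i2])
    grp[k + 1] <- if (inter_min > resting + burst_margin) grp[k] else grp[k] + 1L
  }
  grp
}

#' Classify a cell by its firing pattern
#'
#' Spikes whose inter-peak potential fails to return to rest form bursts.
#' Cells with bursts only are `"burst"`, with both bursts and single events
#' `"single_and_burst"`, with singles only `"single"`. A cell with no spikes
#' is `"non_spiking"` only if a current-step protocol (steps of +10 pA up to
#' +150 pA) produced no spikes either; without step data the label is
#' indeterminate and flagged.
#'
#' @param trace A `vm_trace`.
#' @param spikes Optional pre-computed `spike_events`.
#' @param step_protocol Optional data frame with `step_pA` and `n_spikes`.
#' @param resting Optional resting potential; estimated if missing.
#' @param burst_margin Burst tolerance above rest (mV).
#' @return List of class `cell_classification`: `label`, `n_single`,
#'   `n_burst`, `indeterminate`, `step_protocol`.
#' @export
classify_cell <- function(trace, spikes = NULL, step_protocol = NULL,
                          resting = NULL, burst_margin = 2) {
  if (is.null(spikes)) spikes <- detect_spikes(trace)
  if (is.null(resting)) resting <- estimate_resting_vm(trace, spikes)
  indeterminate <- FALSE
  if (nrow(spikes) == 0) {
    step_spikes <- if (!is.null(step_protocol)) sum(step_protocol$n_spikes) else NA
    if (is.null(step_protocol)) {
      label <- "indeterminate"; indeterminate <- TRUE
    } else if (step_spikes == 0 && max(step_protocol$step_pA) >= 150) {
      label <- "non_spiking"
    } else if (step_spikes == 0) {
      label <- "indeterminate"; indeterminate <- TRUE  # steps did not reach +150 pA
    } else {
      label <- "single"  # fires only under current injection
    }
    n_single <- 0L; n_burst <- 0L
  } else {
    grp <- group_bursts(trace, spikes, resting, burst_margin)
    sizes <- tabulate(grp)
    n_burst <- sum(sizes >= 2)
    n_single <- sum(sizes == 1)
    label <- if (n_burst > 0 && n_single > 0) "single_and_burst"
             else if (n_burst > 0) "burst" else "single"
  }
  structure(list(label = label, n_single = n_single, n_burst = n_burst,
                 indeterminate = indeterminate,
                 step_protocol = step_protocol,
                 resting_vm = resting),
            class = "cell_classification")
}

#' @export
print.cell_classification <- function(x, ...) {
  cat(sprintf("<cell_classification> %s (singles: %d, bursts: %d)%s\n",
              x$label, x$n_single, x$n_burst,
              if (x$indeterminate) " [indeterminate]" else ""))
  invisible(x)
}

#' Light-evoked membrane-potential change, constant-light regime
#'
#' Window means of the raw trace (spikes are not excised): `pre_mean` over
#' the 60 s before light onset, `stim_mean` over the first 60 s of light,
#' `post_mean` over the final 60 s of the recording provided that window
#' starts at least 60 s after light off (otherwise the post fields are
#' missing while the stimulation change is still reported).
#'
#' @param trace A `vm_trace` with a constant-light annotation.
#' @return List of class `vm_response_summary` with `pre_mean`, `stim_mean`,
#'   `post_mean` (mV), `dvm_stim = stim - pre`, `dvm_post = post - pre`, and
#'   `regime = "constant"`.
#' @export
vm_response_constant <- function(trace) {
  stopifnot(inherits(trace, "vm_trace"))
  if (is.null(trace$light) || trace$light$mode != "constant") {
    stop_format("trace lacks a constant-light annotation")
  }
  fs <- trace$fs
  n <- length(trace$vm)
  on_i <- as.integer(round(trace$light$onset_s * fs)) + 1L
  off_i <- as.integer(round((trace$light$onset_s + trace$light$duration_s) * fs))
  n60 <- as.integer(round(60 * fs))
  if (on_i - n60 < 1L || off_i > n) {
    stop_format("trace must cover 60 s baseline and the light epoch")
  }
  pre <- mean(trace$vm[(on_i - n60):(on_i - 1L)])
  stim <- mean(trace$vm[on_i:(on_i + n60 - 1L)])
  post <- NA_real_
  if (n - n60 + 1L >= off_i + n60) {
    post <- mean(trace$vm[(n - n60 + 1L):n])
  }
  structure(list(pre_mean = pre, stim_mean = stim, post_mean = post,
                 dvm_stim = stim - pre, dvm_post = post - pre,
                 regime = "constant"),
            class = "vm_response_summary")
}

#' Composite pulse-evoked membrane potential
#'
#' Averages the 1 s epochs following every light-pulse onset pointwise into a
#' composite waveform (nominally 120 pulses) and reports the mean of its
#' first 100 ms — the pulsed-regime response measure.
#'
#' @param trace A `vm_trace` with pulsed-light annotation.
#' @param pulse_onsets Optional onsets (s); taken from the annotation by
#'   default.
#' @return List of class `pulse_composite_vm`: `t_rel`, `composite` (mV),
#'   `n_pulses`, `first100ms_mean`.
#' @export
composite_pulse_vm <- function(trace, pulse_onsets = NULL) {
  stopifnot(inherits(trace, "vm_trace"))
  onsets <- pulse_onsets %||% trace$light$pulse_onsets
  if (is.null(onsets) || length(onsets) == 0) {
    stop_format("no pulse onsets annotated")
  }
  fs <- trace$fs
  len <- as.integer(round(1 * fs))
  epochs <- list()
  for (p in onsets) {
    i0 <- as.integer(round(p * fs)) + 1L
    if (i0 + len - 1L > length(trace$vm)) next
    epochs[[length(epochs) + 1L]] <- trace$vm[i0:(i0 + len - 1L)]
  }
  if (length(epochs) < 2) {
    stop_insufficient("need >= 2 complete 1 s epochs")
  }
  composite <- Reduce(`+`, epochs) / length(epochs)
  t_rel <- (seq_len(len) - 1L) / fs
  structure(list(t_rel = t_rel, composite = composite,
                 n_pulses = length(epochs),
                 first100ms_mean = mean(composite[t_rel < 0.1])),
            class = "pulse_composite_vm")
}

#' Light-evoked membrane-potential change, pulsed regime
#'
#' The pulsed-regime response is the composite first-100-ms mean relative to
#' the 60 s pre-light baseline mean.
#'
#' @param trace A `vm_trace` with pulsed-light annotation.
#' @return A `vm_response_summary` with `regime = "pulsed"`.
#' @export
vm_response_pulsed <- function(trace) {
  comp <- composite_pulse_vm(trace)
  fs <- trace$fs
  on_i <- as.integer(round(trace$light$onset_s * fs)) + 1L
  n60 <- as.integer(round(60 * fs))
  if (on_i - n60 < 1L) stop_format("trace must cover a 60 s baseline")
  pre <- mean(trace$vm[(on_i - n60):(on_i - 1L)])
  n <- length(trace$vm)
  off_i <- as.integer(round((trace$light$onset_s + trace$light$duration_s) * fs))
  post <- if (n - n60 + 1L >= off_i + n60) mean(trace$vm[(n - n60 + 1L):n]) else NA_real_
  structure(list(pre_mean = pre, stim_mean = comp$first100ms_mean,
                 post_mean = post,
                 dvm_stim = comp$first100ms_mean - pre,
                 dvm_post = post - pre, regime = "pulsed"),
            class = "vm_response_summary")
}

#' @export
print.vm_response_summary <- function(x, ...) {
  cat(sprintf("<vm_response_summary> %s: dVm stim %+.2f mV, post %+.2f mV\n",
              x$regime, x$dvm_stim, x$dvm_post))
  invisible(x)
}

#' Secondary spikes after light-evoked action potentials
#'
#' For each pulse whose first spike falls within 50 ms of the pulse onset
#' (an evoked spike), counts additional spikes in the 100-500 ms window after
#' that first spike. Reliability is the fraction of evoked pulses followed by
#' at least one such secondary spike; missing when no pulse evoked a spike.
#'
#' @param trace A `vm_trace` with pulsed-light annotation.
#' @param spikes Optional pre-computed `spike_events`.
#' @param window_ms Secondary-spike window after the first evoked spike (ms).
#' @return List: `per_pulse` data frame (`pulse_onset`, `evoked`,
#'   `n_secondary`), `reliability`, `n_evoked`.
#' @export
detect_secondary_spikes <- function(trace, spikes = NULL,
                                    window_ms = c(100, 500)) {
  if (is.null(spikes)) spikes <- detect_spikes(trace)
  onsets <- trace$light$pulse_onsets
  if (is.null(onsets) || length(onsets) == 0) {
    stop_format("no pulse onsets annotated")
  }
  st <- spikes$peak_time
  evoked <- logical(length(onsets))
  n_sec <- integer(length(onsets))
  for (k in seq_along(onsets)) {
    first <- st[st >= onsets[k] & st < onsets[k] + 0.05]
    if (length(first) == 0) next
    evoked[k] <- TRUE
    t1 <- first[1]
    n_sec[k] <- sum(st > t1 + window_ms[1] / 1000 &
                    st <= t1 + window_ms[2] / 1000)
  }
  rel <- if (any(evoked)) mean(n_sec[evoked] >= 1) else NA_real_
  list(per_pulse = data.frame(pulse_onset = onsets, evoked = evoked,
                              n_secondary = n_sec),
       reliability = rel, n_evoked = sum(evoked))
}

#' Intra-burst inter-spike interval
#'
#' Time between the first and second peak of a volley, in ms; missing with
#' fewer than two spikes.
#'
#' @param spike_times Peak times (s) of one volley, ascending.
#' @return ISI in ms, or `NA`.
#' @export
burst_isi <- function(spike_times) {
  if (length(spike_times) < 2) return(NA_real_)
  (spike_times[2] - spike_times[1]) * 1000
}
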