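#' Decimate an LFP trace for time-frequency analysis
#'
#' Anti-alias filters and downsamples to `target_fs` (integer ratio). The
#' 1-15 Hz analysis band sits far below the 500 Hz default target, so
#' decimation is lossless for the quantities computed here while making the
#' wavelet transform tractable.
#'
#' @param trace An `lfp_trace`.
#' @param target_fs Target rate (Hz).
#' @return The decimated `lfp_trace` (unchanged if already at or below
#'   `target_fs`).
#' @export
decimate_lfp <- function(trace, target_fs = 500) {
  stopifnot(inherits(trace, "lfp_trace"))
  if (trace$fs <= target_fs) return(trace)
  q <- trace$fs / target_fs
  if (abs(q - round(q)) > 1e-9) {
    stop_format("fs must be an integer multiple of target_fs")
  }
  y <- signal::decimate(trace$signal, round(q), ftype = "iir")
  out <- trace
  out$signal <- as.numeric(y)
  out$fs <- target_fs
  out
}

#' Complex Morlet kernel: `width` cycles at frequency f, Gaussian envelope
#' truncated at +/- `cutoff` SD, normalised to unit energy.
#' @noRd
morlet_kernel <- function(f, fs, width = 30, cutoff = 3) {
  sd_t <- width / (2 * pi * f)
  K <- as.integer(floor(cutoff * sd_t * fs))
  t <- (-K:K) / fs
  w <- exp(-t^2 / (2 * sd_t^2)) * exp(2i * pi * f * t)
  w / sqrt(sum(Mod(w)^2))
}

#' Morlet wavelet spectrogram over 1-15 Hz
#'
#' Convolves the (decimated) signal with complex Morlet wavelets of `width`
#' cycles per frequency, Gaussian envelope truncated at `gauss_sd_cutoff`
#' standard deviations, on a 0.1 Hz grid from 1 to 15 Hz (141 bins). Power is
#' the squared coefficient magnitude. Samples closer to either trace edge
#' than half the wavelet support are masked invalid at that frequency; if the
#' trace is shorter than the 1 Hz wavelet the affected rows are fully masked
#' with a warning.
#'
#' @param trace An `lfp_trace`; decimated to `analysis_fs` first when
#'   sampled faster.
#' @param freqs Frequency grid (Hz), default `seq(1, 15, by = 0.1)`.
#' @param width Wavelet width in cycles, default 30.
#' @param gauss_sd_cutoff Envelope truncation (SD), default 3.
#' @param analysis_fs Rate the signal is decimated to before the transform.
#' @param time_step Spacing (s) of retained time points, default 0.01 s;
#'   `NULL` keeps every sample.
#' @return List of class `wavelet_spectrogram`: `freqs`, `times` (s),
#'   `power` (freq x time matrix), `valid` (logical matrix), `fs`.
#' @export
morlet_spectrogram <- function(trace, freqs = seq(1, 15, by = 0.1),
                               width = 30, gauss_sd_cutoff = 3,
                               analysis_fs = 500, time_step = 0.01) {
  stopifnot(inherits(trace, "lfp_trace"))
  trace <- decimate_lfp(trace, analysis_fs)
  fs <- trace$fs
  x <- trace$signal
  n <- length(x)
  keep <- if (is.null(time_step)) seq_len(n) else {
    step <- max(1L, as.integer(round(time_step * fs)))
    seq(1L, n, by = step)
  }
  times <- (keep - 1L) / fs
  power <- matrix(NA_real_, nrow = length(freqs), ncol = length(keep))
  valid <- matrix(FALSE, nrow = length(freqs), ncol = length(keep))
  warned <- FALSE
  for (j in seq_along(freqs)) {
    w <- morlet_kernel(freqs[j], fs, width, gauss_sd_cutoff)
    K <- (length(w) - 1L) / 2L
    if (2L * K + 1L > n) {
      if (!warned) {
        warning("trace shorter than the wavelet support at ",
                freqs[j], " Hz; rows masked")
        warned <- TRUE
      }
      next
    }
    N <- stats::nextn(n + length(w) - 1L, 2)
    conv <- fft(fft(c(x, rep(0, N - n))) *
                  fft(c(w, rep(0, N - length(w)))), inverse = TRUE) / N
    coef <- conv[(K + 1L):(K + n)]  # centre-aligned coefficients
    p <- Mod(coef)^2
    ok <- keep > K & keep <= n - K
    power[j, ] <- p[keep]
    valid[j, ok] <- TRUE
  }
  structure(list(freqs = freqs, times = times, power = power,
                 valid = valid, fs = fs, width = width,
                 gauss_sd_cutoff = gauss_sd_cutoff),
            class = "wavelet_spectrogram")
}

#' @export
print.wavelet_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<wavelet_spectrogram> %d freqs (%.1f-%.1f Hz) x %d times, %.0f%% valid\n",
    length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
    100 * mean(x$valid)))
  invisible(x)
}

#' Normalise a spectrogram to its pre-stimulus baseline
#'
#' Per-frequency mode (used for statistics): each 0.1 Hz row is divided by
#' its mean baseline power and 1 is subtracted, so the baseline maps to 0 and
#' positive values during stimulation denote a power increase. Global mode
#' (used for display averaging across flies, whose raw wavelet magnitudes
#' differ): the whole matrix is divided by the grand baseline mean.
#' Frequencies with zero baseline power are masked.
#'
#' @param spec A `wavelet_spectrogram`.
#' @param baseline_window `c(start_s, end_s)` of the pre-stimulus segment.
#' @param mode `"per_frequency"` or `"global"`.
#' @return The spectrogram with `power` replaced by baseline-zeroed ratios
#'   (`ratio = TRUE` flag set).
#' @export
normalize_to_baseline <- function(spec, baseline_window,
                                  mode = c("per_frequency", "global")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "wavelet_spectrogram"))
  bl <- spec$times >= baseline_window[1] & spec$times < baseline_window[2]
  if (!any(bl)) stop_format("baseline window contains no samples")
  out <- spec
  if (mode == "per_frequency") {
    for (j in seq_along(spec$freqs)) {
      ok <- bl & spec$valid[j, ]
      m <- if (any(ok)) mean(spec$power[j, ok]) else 0
      if (!is.finite(m) || m <= 0) {
        out$valid[j, ] <- FALSE
        out$power[j, ] <- NA_real_
      } else {
        out$power[j, ] <- spec$power[j, ] / m - 1
      }
    }
  } else {
    ok <- sweep(spec$valid, 2, bl, `&`)
    m <- mean(spec$power[ok])
    if (!is.finite(m) || m <= 0) stop_format("zero global baseline power")
    out$power <- spec$power / m - 1
  }
  out$ratio <- TRUE
  out$baseline_window <- baseline_window
  out
}

#' Mean stimulation-period wavelet ratio in a frequency band
#'
#' One scalar per fly: the mean baseline-zeroed ratio over valid
#' time-frequency samples inside the band and the stimulation window.
#' Positive values denote a power increase over baseline.
#'
#' @param spec_ratios A baseline-normalised `wavelet_spectrogram`.
#' @param band `c(lo, hi)` Hz, default `c(1, 15)`.
#' @param stim_window `c(start_s, end_s)` of the stimulation period.
#' @return Mean ratio (NA when the selection is fully masked), with
#'   attribute `n` (valid samples used).
#' @export
band_power_ratio <- function(spec_ratios, band = c(1, 15), stim_window) {
  stopifnot(inherits(spec_ratios, "wavelet_spectrogram"))
  if (is.null(spec_ratios$ratio)) {
    stop_contract("spectrogram must be baseline-normalised first")
  }
  fi <- spec_ratios$freqs >= band[1] & spec_ratios$freqs <= band[2]
  ti <- spec_ratios$times >= stim_window[1] & spec_ratios$times < stim_window[2]
  sel <- spec_ratios$valid[fi, ti, drop = FALSE]
  vals <- spec_ratios$power[fi, ti, drop = FALSE][sel]
  if (length(vals) == 0) return(structure(NA_real_, n = 0L))
  structure(mean(vals), n = length(vals))
}

#' Pulse-evoked field-potential peak amplitude
#'
#' Each trial is re-zeroed by subtracting its mean over the 50 ms before the
#' pulse; the trial peak is the maximum absolute deviation within the 50 ms
#' after pulse onset, and the summary is the mean over all complete trials
#' (nominally 120). Fewer than 10 complete trials flags the summary `low_n`.
#'
#' @param trace An `lfp_trace`.
#' @param pulse_onsets Pulse onsets (s); taken from the light annotation by
#'   default.
#' @param window_ms Post-onset search window (ms), default 50.
#' @return List of class `erp_summary`: `per_trial` (data frame
#'   `pulse_onset`, `peak`), `mean_peak`, `n_trials`, `low_n`.
#' @export
erp_peak_amplitude <- function(trace, pulse_onsets = NULL, window_ms = 50) {
  stopifnot(inherits(trace, "lfp_trace"))
  onsets <- pulse_onsets %||% trace$light$pulse_onsets
  if (is.null(onsets) || length(onsets) == 0) {
    stop_format("no pulse onsets given or annotated")
  }
  fs <- trace$fs
  nw <- as.integer(round(window_ms / 1000 * fs))
  peaks <- numeric(0); used <- numeric(0)
  for (p in onsets) {
    oi <- as.integer(round(p * fs)) + 1L
    if (oi - nw < 1L || oi + nw - 1L > length(trace$signal)) next
    base <- mean(trace$signal[(oi - nw):(oi - 1L)])
    seg <- trace$signal[oi:(oi + nw - 1L)] - base
    peaks <- c(peaks, max(abs(seg)))
    used <- c(used, p)
  }
  structure(list(per_trial = data.frame(pulse_onset = used, peak = peaks),
                 mean_peak = if (length(peaks)) mean(peaks) else NA_real_,
                 n_trials = length(peaks),
                 low_n = length(peaks) < 10),
            class = "erp_summary")
}

#' @export
print.erp_summary <- function(x, ...) {
  cat(sprintf("<erp_summary> mean peak %.2f over %d trials%s\n",
              x$mean_peak, x$n_trials, if (x$low_n) " [low n]" else ""))
  invisible(x)
}
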